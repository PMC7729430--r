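Package: steroidite
Title: Individualized Treatment Effects of Corticosteroids in Septic Shock
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimation pipeline for average and individual treatment
    effects of corticosteroid regimens (hydrocortisone, with or without
    fludrocortisone) on 90-day and 28-day mortality in septic shock,
    pooled across multi-trial randomized cohorts. Implements targeted
    maximum likelihood estimation of the average treatment effect,
    per-patient treatment-effect estimation via a SAPS II baseline-risk
    model and via a cross-validated Super Learner stacking ensemble
    ('optimal individual model'), decision-curve analysis with net
    benefit over a grid of number-willing-to-treat values, model
    evaluation (cross-validated AUC with DeLong intervals, Brier score,
    calibration), and a pruned recursive-partitioning decision aid. A
    calibrated synthetic multi-trial cohort generator with known
    counterfactual risks makes every stage testable without access to
    the original patient-level trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    MASS,
    mgcv,
    glmnet,
    ranger,
    xgboost,
    e1071,
    kernlab,
    rpart,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
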