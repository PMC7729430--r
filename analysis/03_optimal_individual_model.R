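#!/usr/bin/env Rscript
# Stage 3 — fit and evaluate the optimal individual model.
#
# Cross-validated Super Learner for 90-day mortality given covariates,
# missingness indicators, trial and received treatment. Discrimination is
# compared against the SAPS II equation; calibration and Brier score come
# from the honest out-of-fold ensemble predictions; an external-style
# check uses a freshly generated held-out cohort with shifted (higher)
# mortality, emulating validation in a sicker population. The five-member
# library keeps the ten-fold refitting tractable at this cohort size; the
# full ten-member library is available via default_learner_library().

suppressPackageStartupMessages(library(steroidite))

cohort <- read_cohort("results/cohort.csv")
dir.create("scratch", showWarnings = FALSE)

fsl <- fit_super_learner(cohort, outcome = "y90",
                         library = fast_learner_library(),
                         plan = cv_plan(10, seed = 101))
print(fsl)

y <- cohort$y90
internal <- evaluation_report(fsl$cv_scores, y)
saps_scores <- saps2_baseline_risk(
  ifelse(is.na(cohort$saps2), median(cohort$saps2, na.rm = TRUE),
         cohort$saps2))
saps_eval <- evaluation_report(saps_scores, y)

cat(sprintf("\nOptimal model : CV-AUC %.2f (%.2f-%.2f), Brier %.2f\n",
            internal$auc, internal$auc_ci[1], internal$auc_ci[2],
            internal$brier))
cat(sprintf("SAPS II       : AUC    %.2f (%.2f-%.2f), Brier %.2f\n",
            saps_eval$auc, saps_eval$auc_ci[1], saps_eval$auc_ci[2],
            saps_eval$brier))
cat(sprintf("Mean predicted risk: optimal %.1f%%, SAPS II %.1f%% ",
            100 * mean(fsl$cv_scores), 100 * mean(saps_scores)))
cat(sprintf("(observed %.1f%%)\n", 100 * mean(y)))

# held-out cohort: same process, higher baseline mortality
dgp_ext <- default_dgp(seed = 777L)
dgp_ext$baseline$intercept <- dgp_ext$baseline$intercept + 0.6
held <- apply_missingness(generate_cohort(300, dgp = dgp_ext))
external <- evaluation_report(predict_risk(fsl, held), held$y90)
cat(sprintf("Held-out (n=300, mortality %.1f%%): AUC %.2f (%.2f-%.2f), Brier %.2f\n",
            100 * mean(held$y90), external$auc, external$auc_ci[1],
            external$auc_ci[2], external$brier))

write.csv(internal$calibration, "results/calibration.csv",
          row.names = FALSE)
jsonlite::write_json(
  list(optimal_model = list(cv_auc = internal$auc, ci = internal$auc_ci,
                            brier = internal$brier),
       saps2 = list(auc = saps_eval$auc, ci = saps_eval$auc_ci,
                    brier = saps_eval$brier),
       external = list(auc = external$auc, ci = external$auc_ci,
                       brier = external$brier, n = external$n),
       weights = as.list(fsl$weights)),
  "results/evaluation.json", auto_unbox = TRUE, digits = NA)

saveRDS(fsl, "scratch/optimal_model.rds")
cat("Written: results/evaluation.json, results/calibration.csv,",
    "scratch/optimal_model.rds\n")
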