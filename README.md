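# steroidite

Individualized treatment effects of corticosteroids in septic shock: a
tested R implementation of the full analysis chain from pooled randomized
trials to per-patient treatment decisions.

## What it does

Corticosteroid trials in septic shock disagree on the average benefit,
and the average hides heterogeneity: the same regimen is expected to help
some patients and harm others. This package implements, end to end:

* **Average treatment effect (ATE)** for any contrast of the three arms
  (control, hydrocortisone, hydrocortisone + fludrocortisone) by
  **targeted maximum likelihood estimation (TMLE)** — per trial and
  pooled, reported as relative risk (RR) and absolute risk reduction
  (ARR) with influence-curve 95% CIs.
* **Individual treatment effects (ITE)** two ways:
  * severity model: `ITE = P(Y=1 | A=0, SAPS II) × (1 − RR)`, with
    baseline risk from the published SAPS II equation
    `logit p = −7.7631 + 0.0737·s + 0.9971·ln(s + 1)`;
  * optimal individual model: a from-scratch cross-validated **Super
    Learner** (10-fold, CV-AUC metalearner over a configurable library of
    parametric and machine-learning risk models) whose counterfactual
    predictions are differenced per regimen.
* **Decision-curve analysis**: net benefit
  (`decrease in event rate − treatment rate × T`) of treat-all,
  treat-none, severity-rule and optimal-model-rule strategies across a
  grid of **number willing to treat** values (`NWT = 1/T`), with
  trial-stratified bootstrap bands.
* **Model evaluation**: Mann–Whitney AUC with DeLong CIs, pooled
  cross-validated AUC, Brier score, decile calibration.
* **A pruned CART decision tree** rendering the recommendation at a
  chosen NWT as clinical rules (complexity parameter by the 1-SE rule
  over 20-fold CV).

The original trials' patient-level data are not public, so the package
ships a **synthetic multi-trial cohort generator** with known per-arm
counterfactual risks, calibrated to the pooled cohort's published
marginals (n = 2548 over four two-arm trials; median SAPS II 55 (42–69);
90-day mortality 47.7%). Every estimator is validated against the
generator's ground truth; see `vignettes/individual-treatment-effects.Rmd`
for the methods account.

## Worked example

```r
library(steroidite)

# a calibrated synthetic cohort with informative missingness
cohort <- apply_missingness(generate_cohort(2548, seed = 20260929))
mean(cohort$y90)                       # 0.481  (calibration target 0.477)
median(cohort$saps2)                   # 55.0

# pooled TMLE, any steroid vs placebo, 90-day mortality
est <- tmle_ate(cohort, c("any_steroid", "control"))
print(est)
#> TMLE any_steroid vs control (y90, n=2039)
#>   RR  0.90 (0.83-0.98) p=0.013
#>   ARR 5.05% (1.22%-8.89%) p=0.010

# optimal individual model and per-patient effects
fsl <- fit_super_learner(cohort, "y90", library = fast_learner_library(),
                         plan = cv_plan(10, seed = 101))
fsl$cv_auc                             # 0.76 (SAPS II alone: 0.71)
ite <- ite_optimal(fsl, cohort)
mean(ite$d < 0)                        # ~5% predicted to gain nothing/harm

# net benefit at NWT 25 (threshold T = 0.04)
net_benefit_treat_all(est$arr, nwt_to_threshold(25))   # 0.011
net_benefit_rule(ite$d, 0.04)$net_benefit              # 0.040, treating 77%
```

The numbers shown are the output of the analysis scripts below on this
seed. Interpretation: at NWT 25 treating everybody with hydrocortisone is
barely better than treating no one (net benefit ≈ 0.01, treating 100%),
while treating by the individual model achieves a larger net benefit
while treating a fraction of patients — the qualitative pattern that
motivates individualized treatment rules.

## The analysis workflow

Numbered drivers under `analysis/` run the whole study and write tables
to `results/`:

```sh
Rscript analysis/01_simulate_cohort.R        # cohort + data dictionary
Rscript analysis/02_average_treatment_effects.R  # per-trial & pooled TMLE, y90 & y28
Rscript analysis/03_optimal_individual_model.R   # Super Learner + evaluation
Rscript analysis/04_individual_treatment_effects.R
Rscript analysis/05_net_benefit_curves.R     # curves + plot, NWT 2..100
Rscript analysis/06_decision_tree.R          # rules at NWT 50
```

`run_full_analysis(run_config(...))` performs the same pipeline in one
call with a reproducibility manifest.

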