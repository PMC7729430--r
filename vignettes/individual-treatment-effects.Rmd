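---
title: "Estimating individual treatment effects of corticosteroids in septic shock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating individual treatment effects of corticosteroids in septic shock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Randomized trials of corticosteroids in septic shock report an *average*
treatment effect (ATE): the change in 90-day mortality if every patient,
versus no patient, received the drug. With heterogeneous treatment effects
(HTE) the average hides clinically decisive variation — some patients are
expected to benefit substantially, others to be harmed — so the binary
"treat everyone / treat no one" reading of a trial is not the best
achievable policy. `steroidite` implements the full chain of analyses
needed to move from the ATE to per-patient decisions:

1. **ATE by targeted maximum likelihood (TMLE)** for any contrast of the
   three arms (control, hydrocortisone, hydrocortisone + fludrocortisone),
   per trial and pooled, reported as relative risk (RR) and absolute risk
   reduction (ARR) with influence-curve confidence intervals.
2. **Two individual-treatment-effect (ITE) estimators**: a severity-model
   ITE, `ITE = P(Y=1|A=0, SAPS II) * (1 - RR)`, with the baseline risk from
   the published SAPS II logistic equation
   (`logit p = -7.7631 + 0.0737 s + 0.9971 ln(s+1)`); and an
   "optimal individual model" — a cross-validated Super Learner for
   mortality given covariates, missingness indicators, trial and received
   treatment, whose counterfactual predictions are differenced per regimen.
3. **Decision-curve analysis**: the net benefit of treat-all, treat-none,
   severity-rule and optimal-model-rule strategies across a grid of
   number-willing-to-treat (NWT) values, with bootstrap bands.
4. **A pruned CART decision tree** translating the model's recommendation
   at a chosen NWT into legible clinical rules.

Because the four source trials' patient-level data are not public, every
stage runs against a **synthetic multi-trial cohort generator** with known
counterfactual risks, calibrated to the pooled cohort's published
marginals. The generator is first-class, tested code: it is what makes the
estimators' operating characteristics checkable.

## The synthetic cohort generator

`default_covariate_specs()` defines 14 baseline covariates. Where the
pooled cohort publishes a marginal — age 66 (55–76), 65% men, SAPS II 55
(42–69), SOFA 11 (9–13) — the continuous family (truncated normal or
shifted log-normal) is solved numerically so its quartiles match the
printed median and IQR (`fit_marginal()`; two parameters against three
quantile targets, so the fit is a least-squares compromise within half a
point when the printed IQR is slightly asymmetric). The remaining
marginals (adrenal status, lactate, glucose, norepinephrine dose,
infection characteristics, ventilation) use values typical of published
septic-shock trial baseline tables. Covariates are drawn independently:
inter-covariate correlations are not published, so any correlation
structure would be a modeling invention; we prefer the transparent
independent design and note that it makes the prediction task slightly
easier than real data.

`default_dgp()` fixes the outcome process:

* **Trials**: four trials sized 299/499/509/1241, each randomizing two of
  the three arms 1:1 exactly as in the source designs (only one trial
  randomized hydrocortisone against the combination; it has no placebo
  arm). Trial-specific intercepts (+0.45, −0.35, −0.10, 0 log-odds) give
  the trials different baseline mortality.
* **Control-arm risk**: logistic in severity (SAPS II 0.048/point, SOFA
  0.10/point), age, lactate, norepinephrine dose, ventilation, adrenal
  response and admission category. The global intercept is calibrated by
  root-finding over a 200,000-draw Monte-Carlo integral
  (`calibrate_baseline_intercept()`) so pooled marginal 90-day mortality
  equals 47.7%; the solved value (−0.433) is frozen in the package.
* **Treatment effects**: log-odds shifts of −0.30 (hydrocortisone) and
  −0.26 (combination), interacting with the cortisol increment after
  corticotropin (+0.020 and +0.018 per µg/dL above 9) and with SAPS II
  (−0.008 and −0.006 per point above 55). The cortisol interaction is
  qualitative: corticotropin responders with large increments are pushed
  past zero into expected harm (about 14% of patients under the defaults),
  while sicker patients benefit more. This encodes the premise that the
  two regimens' effects can go in opposite directions across patients,
  which the severity-model ITE cannot express by construction.
* **Endpoints**: `y28 = y90 AND Bernoulli(0.8)` — 80% of 90-day deaths
  occur by day 28, enforcing nesting of the endpoints.
* **Missingness**: adrenal-axis labs are missing ~25% — with the
  probability for the cortisol increment *decreasing in its own value*
  (missing not at random) — lactate ~10% and glucose ~8% at random.
  `apply_missingness()` blanks values and sets `miss_*` indicators;
  outcomes and treatment are never blanked.

A single master seed drives per-stage substreams (`derive_seed()`), so a
cohort is a pure function of `(specs, dgp, n, seed)` and regeneration is
byte-identical.

What passing tests on this generator do **not** show: performance under
correlated covariates, measurement error, time-varying confounding, or
model misspecification beyond what the scenarios construct. The generator
reproduces printed *marginals*, not the joint distribution of the real
trials.

## Targeted maximum likelihood

`tmle_ate()` is a standard one-step TMLE for a binary outcome: initial
outcome regressions under both arms (a trial-adjusted logistic regression
by default, or ensemble counterfactual predictions via `fsl =`), a single
clever covariate `H = A/g − (1−A)/(1−g)`, and a one-dimensional logistic
fluctuation with the initial logit-risk as offset. We solve the
fluctuation by Newton iterations to `|score| < 1e-12·n` rather than an
off-the-shelf `glm`, so the efficient-score equation holds to machine
precision and the influence-curve mean is numerically zero. Both ARR
(`mean0 − mean1`; positive favors treatment since the outcome is death)
and RR (`mean1/mean0`) come from the same pair of targeted means — one
procedure, two estimands — with the RR interval on the log scale by the
delta method.

Numerical and design choices:

* In randomized cohorts `g` is **known** from the per-trial randomization
  table; an estimated-`g` logistic option exists for observational use.
  `g` is truncated to [0.01, 0.99]; a structural `g` of exactly 0 or 1 is
  an error, except that trials which never randomized one side of a
  contrast are excluded from it up front (they carry no information about
  that contrast — the combination-vs-hydrocortisone trial has no placebo
  arm, so it is skipped in any placebo contrast, mirroring the per-trial
  table layout).
* Initial predictions are clipped to `[1e-3, 1−1e-3]` before any logit,
  for fluctuation stability.
* The pooled estimate adjusts for trial as a covariate in the initial
  fit (the default); per-stratum estimates are returned alongside by
  `pooled_and_per_trial()` for a stratified reading.
* p-values are two-sided Wald statistics on each estimand's scale.

## The Super Learner and its metalearner

`fit_super_learner()` is a from-scratch cross-validated stacking
ensemble. The default ten-member library spans the parametric learners
(logistic regression with and without treatment interactions, stepwise
AIC selection, and a ridge-penalized logistic regression — the posterior
mode under a Gaussian coefficient prior — standing in for a Bayesian GLM)
and nonparametric ones (GAM, a first-degree hinge-basis lasso in the
spirit of MARS, gradient boosting, random forest, linear and RBF support
vector machines). Treatment enters as a three-level factor, with explicit
treatment × (SAPS II, cortisol increment) columns for the parametric
learners — a model with no treatment interactions cannot express
qualitative HTE. Missing values are median/mode-imputed using training
statistics frozen in the `feature_map`, and the binary missingness
indicators stay in the design so informative missingness remains visible
to the learners.

The level-1 matrix is built by fold-wise refitting (10 stratified folds
by default), so every out-of-fold prediction is honest. The metalearner
maximizes the cross-validated AUC of the convex combination of level-1
columns. AUC is piecewise constant in the weights, so
`optimize_weights()` uses a fixed deterministic multistart: every simplex
vertex and the uniform vector are scored under the exact tied-pair AUC,
then Nelder–Mead refinements on softmax-parameterized weights optimize a
rank-smoothed surrogate (a logistic kernel over case–control score
differences, pair-subsampled for large n) and are re-scored under the
exact AUC. Ties keep the first candidate found, which makes the result
reproducible and guarantees the ensemble never scores below its best
member. Discrete selection (`metalearner = "discrete"`) is available
where a single-learner choice is preferred; the convex combination is the
default.

A learner that fails in any fold is dropped with a warning and the
optimizer redistributes its mass over the survivors; the fit errors only
if every learner fails. `fast_learner_library()` (both logistic forms,
GAM, random forest, gradient boosting) is used for the repeated
simulation studies and the analysis scripts: it keeps parametric and
flexible coverage at a small fraction of the cost of the ten-member
library at these cohort sizes.

## Individual treatment effects

`ite_saps2()` is the severity-model estimator `p0 (1 − RR)` with `p0`
always from the SAPS II equation — never from the ensemble — keeping the
two strategies genuinely distinct. The per-regimen RRs default to the
pooled empirical values (0.88 hydrocortisone, 0.92 combination) and are
configurable. By construction this ITE is monotone in severity and
single-signed across patients.

`ite_optimal()` differences the ensemble's counterfactual predictions:
`ARR_a = risk(control) − risk(a)` per active regimen; `D` is the maximum
over regimens and the recommended regimen attains it, with ties broken
toward hydrocortisone alone (the lower-exposure regimen). It can and does
take both signs under the default generator. Individual-level confidence
intervals are deliberately not produced; only distributional summaries
are reported.

## Net benefit and the number willing to treat

A decision threshold `T` on the individual risk-difference scale encodes
treatment harm; its inverse is the number willing to treat
(`NWT = 1/T`, so `T = 10%` means NWT 10). Net benefit is the decrease in
event rate minus the treated fraction times `T`; treating no one is the
zero reference. For rule strategies we read the formula
`ITE − P[ITE > T] × T` with the first term as the population-average
event-rate decrease `E[D·1{D > T}]` — not the mean of `D` among the
treated — because only that reading agrees with the decrease-in-event-rate
definition and collapses correctly to treat-all as `T → 0` (when all
effects are positive) and to treat-none as `T` exceeds every effect.
`net_benefit_rule()` therefore returns
`mean(D·1{D>t}) − mean(1{D>t})·t`.

`oracle_net_benefit()` is the simulation ground truth and is defined on
the *expected* potential outcomes — the true per-arm risks carried by the
synthetic cohort — rather than realized binary potential outcomes. Under
this definition the threshold rule "treat iff true `D_i > t`" is exactly
optimal among all covariate-measurable assignments (verified by
exhaustive enumeration in the test suite); a realized-outcome variant
would be optimal only in expectation.

`net_benefit_curves()` evaluates each strategy over an NWT grid (default
integers 2–100, spanning harm assumptions from severe to negligible; 25
is the pivotal value where treat-all crosses zero under the pooled ARR of
about 5%) with percentile bootstrap bands (default B = 500) from
patient-level resampling stratified by trial. Resampling draws from
stratum-sorted values, so the bands are invariant to patient ordering and
reproducible under a fixed seed. These bands reflect sampling of patients
with the effect estimates held fixed; they do not propagate model-fitting
uncertainty.

## Decision tree

`fit_tree()` labels each patient treat / don't-treat by `D_i > t` at the
chosen NWT and fits a CART classification tree (Gini impurity) on
baseline covariates, pruned by cost-complexity with the penalty chosen by
the 1-SE rule over 20-fold cross-validation — the standard choice where
the selection rule is otherwise unspecified. A regression tree on `D`
itself is available (`mode = "regression"`); classification on the
recommendation is the default because the deliverable is a treat /
don't-treat aid. Single-class labels return a root-only tree with a
warning rather than an error.

## Evaluation

`delong_auc_ci()` computes the Mann–Whitney AUC from midranks (tied pairs
count one half, matching exhaustive pair enumeration exactly) with the
DeLong variance from per-case and per-control placement values.
`cross_validated_auc()` reports the AUC of the *pooled* out-of-fold
prediction vector with a single DeLong interval — matching single-number
reporting — rather than averaging fold-wise AUCs; folds are stratified on
the outcome so no training fold is single-class. `brier_score()` is the
mean squared probability error, and `calibration_curve()` uses
equal-frequency deciles with Wilson intervals plus a lowess smooth for
plotting.

## Problem sizes and tolerances in the test suite

The suite exercises: generator calibration at the pooled size (n = 2548,
ten seeds); TMLE parameter recovery at a known risk difference of 0.05
over 500 replicates of n = 1000 with nominal-coverage bounds of 93–97%;
Super Learner oracle behavior on three n = 800 scenarios (linear,
nonlinear, pure-interaction) with the five-member library; exhaustive
2^10 enumeration for rule optimality; and exact identities (TMLE collapse
to the difference in proportions without covariates, DeLong vs.
enumeration to 1e-12). These sizes were chosen to make Monte-Carlo error
small relative to the asserted tolerances while keeping the suite quick
to run routinely.

## Known limitations

* The generator draws covariates independently and encodes HTE through
  two interactions only; real effect modification is surely richer.
* `ITE_SAPS2` inherits the SAPS II equation's overestimation of mortality
  (visible in the analysis scripts: mean predicted ≈ 55% vs. observed
  ≈ 48%), which inflates the severity rule's apparent net benefit — the
  same caveat applies to the original severity-based strategy.
* Net-benefit bands condition on the fitted effect estimates.
* No time-to-event modeling: mortality is binary at fixed horizons.
* The printed real-data performance numbers (AUC 0.64/0.74/0.77, Brier
  0.21/0.28, net benefit 0.31 at NWT 25) depend on the original trial
  data and are not reproduction targets here; the synthetic defaults land
  in the same regime, which is what makes the workflow's behavior
  interpretable.
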