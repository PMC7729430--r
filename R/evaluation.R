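#' Mann-Whitney AUC
#'
#' Area under the ROC curve computed from midranks; tied case-control
#' pairs count one half, matching exhaustive pairwise enumeration exactly.
#'
#' @param scores numeric risk scores.
#' @param y binary outcomes.
#' @return AUC in `[0, 1]`.
#' @export
auc_mann_whitney <- function(scores, y) {
  y <- as.integer(y)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("both outcome classes required for AUC", call. = FALSE)
  r <- rank(scores)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' AUC with a DeLong 95% confidence interval
#'
#' Nonparametric AUC variance from the DeLong structural components
#' (per-case and per-control placement values); Wald interval clipped to
#' `[0, 1]`.
#'
#' @param scores numeric risk scores.
#' @param y binary outcomes (both classes present).
#' @param conf confidence level (default 0.95).
#' @return List with `auc`, `se`, `ci` (length-2), `n1`, `n0`.
#' @export
delong_auc_ci <- function(scores, y, conf = 0.95) {
  y <- as.integer(y)
  cases <- scores[y == 1L]; controls <- scores[y == 0L]
  m <- length(cases); n <- length(controls)
  if (m == 0L || n == 0L)
    stop("both outcome classes required for DeLong CI", call. = FALSE)
  all_r <- rank(c(cases, controls))
  v10 <- (all_r[seq_len(m)] - rank(cases)) / n          # placements of cases
  v01 <- 1 - (all_r[m + seq_len(n)] - rank(controls)) / m
  auc <- mean(v10)
  se <- sqrt(stats::var(v10) / m + stats::var(v01) / n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  list(auc = auc, se = se,
       ci = pmin(pmax(auc + c(-1, 1) * z * se, 0), 1),
       n1 = m, n0 = n)
}

#' Cross-validated AUC of a model-fitting procedure
#'
#' Refits the supplied procedure per fold and pools the out-of-fold
#' predictions into a single vector; the AUC of that pooled vector is
#' reported with a DeLong interval (single-number reporting with one CI).
#'
#' @param data predictor data.frame.
#' @param y binary outcome.
#' @param fitter `function(train_data, train_y)` returning a
#'   `function(newdata) -> scores`.
#' @param plan a [cv_plan()]; folds are stratified on `y` so no fold is
#'   single-class.
#' @return List with `cv_auc`, `ci`, `oof` (pooled out-of-fold scores),
#'   `folds`.
#' @export
cross_validated_auc <- function(data, y, fitter, plan = cv_plan()) {
  folds <- make_folds(y, plan$n_folds, plan$seed, stratified = TRUE)
  oof <- rep(NA_real_, length(y))
  for (f in seq_len(plan$n_folds)) {
    tr <- folds != f
    pred <- fitter(data[tr, , drop = FALSE], y[tr])
    oof[!tr] <- pred(data[!tr, , drop = FALSE])
  }
  d <- delong_auc_ci(oof, y)
  list(cv_auc = d$auc, ci = d$ci, oof = oof, folds = folds)
}

#' Brier score
#'
#' Mean squared difference between predicted probability and outcome.
#'
#' @param scores predicted probabilities in `[0, 1]`.
#' @param y binary outcomes.
#' @return Scalar in `[0, 1]`.
#' @export
brier_score <- function(scores, y) {
  stopifnot(all(scores >= 0 & scores <= 1))
  mean((scores - as.numeric(y))^2)
}

# Wilson score interval for a binomial proportion
wilson_ci <- function(k, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(ctr - hw, ctr + hw)
}

#' Calibration table (and smoothed curve) for predicted risks
#'
#' Equal-frequency bins of predicted risk (deciles by default); per bin the
#' mean prediction, observed event prevalence with a Wilson interval, and
#' the bin count. A lowess-smoothed observed-vs-predicted curve is attached
#' for plotting.
#'
#' @param scores predicted probabilities.
#' @param y binary outcomes.
#' @param bins number of equal-frequency bins (default 10).
#' @return data.frame with columns `bin`, `mean_pred`, `observed`, `n`,
#'   `ci_lo`, `ci_hi`; smoothed curve in `attr(, "smooth")`.
#' @export
calibration_curve <- function(scores, y, bins = 10L) {
  stopifnot(length(scores) >= bins)
  br <- unique(stats::quantile(scores, probs = seq(0, 1, length.out = bins + 1)))
  if (length(br) < 3L) {
    warning("scores nearly constant; returning a single calibration bin")
    ci <- wilson_ci(sum(y), length(y))
    out <- data.frame(bin = 1L, mean_pred = mean(scores),
                      observed = mean(y), n = length(y),
                      ci_lo = ci[1], ci_hi = ci[2])
    attr(out, "smooth") <- NULL
    return(out)
  }
  g <- cut(scores, br, include.lowest = TRUE, labels = FALSE)
  out <- do.call(rbind, lapply(sort(unique(g)), function(b) {
    i <- g == b
    ci <- wilson_ci(sum(y[i]), sum(i))
    data.frame(bin = b, mean_pred = mean(scores[i]), observed = mean(y[i]),
               n = sum(i), ci_lo = ci[1], ci_hi = ci[2])
  }))
  attr(out, "smooth") <- as.data.frame(stats::lowess(scores, as.numeric(y),
                                                     f = 2 / 3))
  out
}

#' Discrimination and calibration report for a risk model
#'
#' @param scores predicted probabilities.
#' @param y binary outcomes.
#' @param bins calibration bins.
#' @return List with `auc`, `auc_ci`, `brier`, `calibration`, `n`.
#' @export
evaluation_report <- function(scores, y, bins = 10L) {
  d <- delong_auc_ci(scores, y)
  list(auc = d$auc, auc_ci = d$ci, brier = brier_score(scores, y),
       calibration = calibration_curve(scores, y, bins), n = length(y))
}
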