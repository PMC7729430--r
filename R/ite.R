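#' Severity-based individual treatment effect
#'
#' The baseline-severity estimator: `ITE = p0 * (1 - RR)` where `p0` is the
#' patient's baseline (untreated) mortality risk and `RR` the treatment's
#' relative risk. Assumes the absolute effect scales linearly with baseline
#' risk, so the ITE is strictly increasing in `p0` for a beneficial
#' treatment (`RR < 1`) and never changes sign across patients.
#'
#' @param p0 baseline risk(s) in `[0, 1]`.
#' @param rr relative risk (> 0).
#' @return Risk difference(s) `p0 * (1 - rr)`.
#' @export
ite_saps2 <- function(p0, rr) {
  stopifnot(all(is.finite(p0)), all(p0 >= 0 & p0 <= 1),
            is.finite(rr), rr > 0)
  p0 * (1 - rr)
}

# pooled empirical relative risks per regimen (90-day mortality); the
# severity strategy multiplies the SAPS II baseline risk by 1 - RR
default_regimen_rr <- function() c(hydrocortisone = 0.88, combination = 0.92)

#' Severity-model ITE for a whole cohort
#'
#' Baseline risk from the SAPS II mortality equation (never from the
#' ensemble, keeping the two strategies distinct), one ARR column per
#' regimen from the configured empirical relative risks. Patients with a
#' missing SAPS II get the median-imputed score.
#'
#' @param cohort a `trial_cohort` (needs a `saps2` column).
#' @param rr named relative risks per regimen.
#' @param model a [saps_risk_model()].
#' @return `ite_estimate` data.frame: `id`, one ARR column per regimen,
#'   `d` (max over regimens), `recommended`.
#' @export
ite_saps2_cohort <- function(cohort, rr = default_regimen_rr(),
                             model = saps_risk_model()) {
  s <- as.numeric(cohort$saps2)
  s[is.na(s)] <- stats::median(s, na.rm = TRUE)
  p0 <- saps2_baseline_risk(s, model)
  out <- data.frame(id = cohort$id %||% seq_len(nrow(cohort)))
  for (a in names(rr)) out[[a]] <- ite_saps2(p0, rr[[a]])
  finish_ite(out, names(rr), method = "saps2")
}

#' Optimal-individual-model ITE
#'
#' Counterfactual risk differences from the Super Learner: for each
#' patient and active regimen, predicted risk under control minus
#' predicted risk under that regimen; `d` is the maximum over regimens and
#' the recommended regimen attains it (ties go to hydrocortisone alone,
#' the lower-exposure regimen). Unlike the severity model, these ITEs can
#' take both signs across patients.
#'
#' @param fsl a `fitted_super_learner` trained with treatment as a feature.
#' @param records patient records.
#' @param arms active regimens to evaluate.
#' @return `ite_estimate` data.frame as in [ite_saps2_cohort()].
#' @export
ite_optimal <- function(fsl, records, arms = ACTIVE_ARMS) {
  if (!isTRUE(fsl$feature_map$has_arm))
    stop("model was not trained with treatment as a feature; ",
         "counterfactual prediction is undefined", call. = FALSE)
  p0 <- predict_risk(fsl, records, arm_override = "control")
  out <- data.frame(id = records$id %||% seq_len(nrow(records)))
  for (a in arms)
    out[[a]] <- p0 - predict_risk(fsl, records, arm_override = a)
  finish_ite(out, arms, method = "optimal")
}

finish_ite <- function(out, arms, method) {
  m <- as.matrix(out[, arms, drop = FALSE])
  out$d <- apply(m, 1, max)
  # ties.method = "first" with hydrocortisone listed first implements the
  # lower-exposure tie-break
  ord <- order(match(arms, c("hydrocortisone", "combination", arms)))
  m2 <- m[, ord, drop = FALSE]
  out$recommended <- colnames(m2)[max.col(m2, ties.method = "first")]
  structure(out, class = c("ite_estimate", "data.frame"), method = method)
}
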