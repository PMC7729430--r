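#' SAPS II hospital-mortality equation
#'
#' The published logistic equation mapping the Simplified Acute Physiology
#' Score II to a probability of death:
#' `logit p = -7.7631 + 0.0737 * s + 0.9971 * ln(s + 1)`.
#' Used here as the baseline risk `P(Y=1 | A=0, SAPS II)` in the
#' severity-based individual-treatment-effect estimator.
#'
#' @param intercept,linear_coef,log_coef model constants; the defaults are
#'   the published values and should not normally be overridden.
#' @return A `saps_risk_model` object.
#' @export
saps_risk_model <- function(intercept = -7.7631, linear_coef = 0.0737,
                            log_coef = 0.9971) {
  structure(list(intercept = intercept, linear_coef = linear_coef,
                 log_coef = log_coef),
            class = "saps_risk_model")
}

#' Baseline 90-day mortality risk from the SAPS II score
#'
#' Evaluates the SAPS II logistic equation; strictly increasing in the
#' score since both coefficients are positive. The natural logarithm is
#' used, per the SAPS II convention. Scores above the conventional maximum
#' of 163 are allowed (the equation is defined everywhere) with a warning.
#'
#' @param saps2 numeric score(s), finite and non-negative.
#' @param model a [saps_risk_model()].
#' @return Probability of death, in (0, 1), one per score.
#' @export
saps2_baseline_risk <- function(saps2, model = saps_risk_model()) {
  if (!is.numeric(saps2) || any(!is.finite(saps2)) || any(saps2 < 0))
    stop("saps2 must be finite and >= 0", call. = FALSE)
  if (any(saps2 > 163))
    warning("SAPS II score above the conventional maximum of 163")
  lp <- model$intercept + model$linear_coef * saps2 +
    model$log_coef * log(saps2 + 1)
  expit(lp)
}
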