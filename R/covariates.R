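#' Covariate specification
#'
#' Describes one baseline covariate's marginal distribution. Continuous
#' covariates use a truncated-normal or shifted log-normal family whose
#' parameters are solved numerically so that the simulated quartiles match a
#' target median and IQR (only median/IQR summaries are available for the
#' pooled septic-shock cohort).
#'
#' @param name covariate name (identifier).
#' @param kind one of `"continuous"`, `"binary"`, `"categorical"`.
#' @param family for continuous: `"truncnorm"` or `"lognormal"`.
#' @param params named numeric parameters: for `truncnorm`
#'   `mu, sigma, lower, upper`; for `lognormal` `mulog, sdlog, shift`;
#'   for binary `prob`.
#' @param levels category labels (categorical only).
#' @param probs category probabilities, summing to 1 (categorical only).
#' @param integer round draws to integers (e.g. SOFA points).
#' @return A `covariate_spec` object.
#' @export
covariate_spec <- function(name, kind, family = NULL, params = NULL,
                           levels = NULL, probs = NULL, integer = FALSE) {
  kind <- match.arg(kind, c("continuous", "binary", "categorical"))
  if (kind == "continuous") {
    if (is.null(family) || is.null(params) || !all(is.finite(unlist(params))))
      stop("covariate '", name, "': continuous marginal needs finite parameters",
           call. = FALSE)
    family <- match.arg(family, c("truncnorm", "lognormal"))
  }
  if (kind == "binary") {
    p <- params[["prob"]]
    if (is.null(p) || !is.finite(p) || p < 0 || p > 1)
      stop("covariate '", name, "': binary marginal needs prob in [0,1]",
           call. = FALSE)
  }
  if (kind == "categorical") {
    if (is.null(levels) || is.null(probs) || length(levels) != length(probs) ||
        abs(sum(probs) - 1) > 1e-8 || any(probs < 0))
      stop("covariate '", name,
           "': categorical levels/probs invalid (must sum to 1)", call. = FALSE)
  }
  structure(list(name = name, kind = kind, family = family, params = params,
                 levels = levels, probs = probs, integer = integer),
            class = "covariate_spec")
}

# quantile function of a truncated normal
qtnorm <- function(p, mu, sigma, lower = -Inf, upper = Inf) {
  plo <- stats::pnorm(lower, mu, sigma)
  phi <- stats::pnorm(upper, mu, sigma)
  stats::qnorm(plo + p * (phi - plo), mu, sigma)
}

#' Solve a continuous marginal from printed median and IQR
#'
#' Finds distribution parameters whose theoretical quartiles best match the
#' printed `q25/q50/q75` (least squares, Nelder-Mead). Two-parameter families
#' against three quantile targets: the fit is exact when the printed summary
#' is compatible with the family and a compromise otherwise.
#'
#' @param q25,q50,q75 target quartiles.
#' @param family `"truncnorm"` or `"lognormal"`.
#' @param lower,upper truncation bounds (truncnorm) .
#' @param shift location shift (lognormal), default 0.
#' @return Named parameter list suitable for [covariate_spec()].
#' @export
fit_marginal <- function(q25, q50, q75, family = c("truncnorm", "lognormal"),
                         lower = -Inf, upper = Inf, shift = 0) {
  family <- match.arg(family)
  stopifnot(q25 < q50, q50 < q75)
  if (family == "truncnorm") {
    obj <- function(par) {
      s <- exp(par[2])
      q <- qtnorm(c(.25, .5, .75), par[1], s, lower, upper)
      sum((q - c(q25, q50, q75))^2)
    }
    start <- c(q50, log((q75 - q25) / 1.349))
    fit <- stats::optim(start, obj, method = "Nelder-Mead",
                        control = list(maxit = 500, reltol = 1e-12))
    list(mu = fit$par[1], sigma = exp(fit$par[2]), lower = lower, upper = upper)
  } else {
    stopifnot(q25 > shift)
    obj <- function(par) {
      q <- shift + exp(par[1] + exp(par[2]) * stats::qnorm(c(.25, .5, .75)))
      sum((q - c(q25, q50, q75))^2)
    }
    start <- c(log(q50 - shift), log((log(q75 - shift) - log(q25 - shift)) / 1.349))
    fit <- stats::optim(start, obj, method = "Nelder-Mead",
                        control = list(maxit = 500, reltol = 1e-12))
    list(mulog = fit$par[1], sdlog = exp(fit$par[2]), shift = shift)
  }
}

# draw n values from one covariate_spec (uses the current RNG stream)
draw_covariate <- function(spec, n) {
  out <- switch(spec$kind,
    continuous = {
      u <- stats::runif(n)
      x <- if (spec$family == "truncnorm") {
        qtnorm(u, spec$params$mu, spec$params$sigma,
               spec$params$lower, spec$params$upper)
      } else {
        spec$params$shift + exp(spec$params$mulog +
                                  spec$params$sdlog * stats::qnorm(u))
      }
      if (isTRUE(spec$integer)) round(x) else x
    },
    binary = stats::rbinom(n, 1L, spec$params$prob),
    categorical = {
      i <- sample.int(length(spec$levels), n, replace = TRUE, prob = spec$probs)
      factor(spec$levels[i], levels = spec$levels)
    }
  )
  out
}

#' Default covariate dictionary for the pooled septic-shock cohort
#'
#' Baseline covariates of the pooled four-trial cohort. Where the pooled
#' summary prints a marginal (age, sex, SAPS II, SOFA) the continuous family
#' is solved to match the printed median and IQR; the remaining marginals
#' (adrenal status, lactate, glucose, norepinephrine dose, ventilation,
#' infection characteristics) use values typical of published septic-shock
#' trial baseline tables.
#'
#' @return Named list of [covariate_spec()] objects.
#' @export
default_covariate_specs <- function() {
  specs <- list(
    covariate_spec("age", "continuous", "truncnorm",
                   fit_marginal(55, 66, 76, "truncnorm", lower = 18, upper = 100)),
    covariate_spec("male", "binary", params = list(prob = 0.65)),
    covariate_spec("admission", "categorical",
                   levels = c("medical", "elective_surgery", "emergency_surgery"),
                   probs = c(0.66, 0.12, 0.22)),
    covariate_spec("saps2", "continuous", "truncnorm",
                   fit_marginal(42, 55, 69, "truncnorm", lower = 0, upper = 163)),
    covariate_spec("sofa", "continuous", "truncnorm",
                   fit_marginal(9, 11, 13, "truncnorm", lower = 0, upper = 24),
                   integer = TRUE),
    covariate_spec("infection_site", "categorical",
                   levels = c("lung", "abdomen", "urinary", "other"),
                   probs = c(0.45, 0.24, 0.12, 0.19)),
    covariate_spec("hospital_acquired", "binary", params = list(prob = 0.35)),
    covariate_spec("pathogen", "categorical",
                   levels = c("gram_positive", "gram_negative", "fungal", "other"),
                   probs = c(0.30, 0.40, 0.05, 0.25)),
    # adrenal status, ug/dL
    covariate_spec("cortisol_baseline", "continuous", "lognormal",
                   fit_marginal(12, 20, 34, "lognormal")),
    covariate_spec("cortisol_increment", "continuous", "lognormal",
                   fit_marginal(2.5, 6, 13, "lognormal")),
    covariate_spec("lactate", "continuous", "lognormal",       # mmol/L
                   fit_marginal(1.8, 3.0, 5.5, "lognormal")),
    covariate_spec("glucose", "continuous", "lognormal",       # mmol/L
                   fit_marginal(6.2, 8.0, 11.0, "lognormal")),
    covariate_spec("norepinephrine", "continuous", "lognormal", # ug/kg/min
                   fit_marginal(0.2, 0.5, 1.1, "lognormal")),
    covariate_spec("mech_vent", "binary", params = list(prob = 0.85))
  )
  names(specs) <- vapply(specs, `[[`, "", "name")
  specs
}
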