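#' Treatment indicator and restriction for an arm contrast
#'
#' A contrast is a pair `c(treated, control)` of arm labels;
#' `"any_steroid"` collapses the two active regimens into one treated
#' group. Returns the cohort restricted to the contrast arms plus the
#' binary indicator.
#' @keywords internal
restrict_contrast <- function(cohort, contrast, trials = NULL) {
  stopifnot(length(contrast) == 2L)
  expand <- function(a) if (a == "any_steroid") ACTIVE_ARMS else a
  treated <- expand(contrast[1]); ref <- expand(contrast[2])
  if (length(intersect(treated, ref)))
    stop("contrast arms overlap", call. = FALSE)
  keep <- cohort$arm %in% c(treated, ref)
  if (!is.null(trials)) {
    # trials that never randomized one side of the contrast contribute no
    # information about it (structural g of 0 or 1): exclude them
    p_t <- rowSums(trials[, treated, drop = FALSE])
    p_r <- rowSums(trials[, ref, drop = FALSE])
    bad <- trials$trial[p_t == 0 | p_r == 0]
    bad <- intersect(bad, unique(as.character(cohort$trial[keep])))
    if (length(bad)) {
      message("excluding trial(s) without both contrast arms: ",
              paste(bad, collapse = ", "))
      keep <- keep & !(cohort$trial %in% bad)
    }
  }
  sub <- cohort[keep, , drop = FALSE]
  list(data = sub, a = as.integer(sub$arm %in% treated),
       treated = treated, ref = ref, idx = which(keep))
}

#' Propensity model for a contrast
#'
#' In randomized cohorts the treatment probability is known by design:
#' per trial, `g = P(treated arms) / P(contrast arms)` from the
#' randomization table. `kind = "estimated"` fits a logistic model of the
#' indicator on baseline covariates instead (observational use).
#'
#' @param kind `"known"` (randomization probabilities) or `"estimated"`.
#' @param trials randomization table (as in [dgp_params()]); if `NULL`
#'   with `kind = "known"`, per-trial empirical assignment frequencies are
#'   used (valid under randomization).
#' @return A `propensity_model` object.
#' @export
propensity_model <- function(kind = c("known", "estimated"), trials = NULL) {
  kind <- match.arg(kind)
  structure(list(kind = kind, trials = trials), class = "propensity_model")
}

# evaluate P(A=1 | W) on the restricted data
propensity_scores <- function(g, rc) {
  data <- rc$data
  if (is.numeric(g)) {
    return(if (length(g) == 1L) rep(g, nrow(data)) else g)
  }
  if (g$kind == "known") {
    tr <- g$trials
    if (!is.null(tr)) {
      p_t <- rowSums(tr[, rc$treated, drop = FALSE])
      p_r <- rowSums(tr[, rc$ref, drop = FALSE])
      gt <- stats::setNames(p_t / (p_t + p_r), tr$trial)
      return(unname(gt[as.character(data$trial)]))
    }
    gt <- tapply(rc$a, as.character(data$trial), mean)
    return(unname(gt[as.character(data$trial)]))
  }
  fm <- feature_map(data)
  fm$has_arm <- FALSE
  des <- build_design(fm, data)
  fit <- stats::glm(rc$a ~ ., binomial(), data = des)
  as.numeric(stats::predict(fit, des, type = "response"))
}

# initial outcome regressions under both arms (logistic, trial-adjusted)
q_init_glm <- function(rc, y, adjust_trial = TRUE) {
  fm <- feature_map(rc$data)
  fm$has_arm <- FALSE
  if (!adjust_trial) fm$has_trial <- FALSE
  des <- build_design(fm, rc$data)
  df <- cbind(des, .a = rc$a, y = y)
  fit <- tryCatch(
    suppressWarnings(stats::glm(y ~ ., binomial(), data = df)),
    error = function(e) NULL)
  if (is.null(fit)) {
    q1 <- rep(mean(y[rc$a == 1]), nrow(des))
    q0 <- rep(mean(y[rc$a == 0]), nrow(des))
  } else {
    nd1 <- df; nd1$.a <- 1L
    nd0 <- df; nd0$.a <- 0L
    q1 <- suppressWarnings(stats::predict(fit, nd1, type = "response"))
    q0 <- suppressWarnings(stats::predict(fit, nd0, type = "response"))
  }
  cbind(q0 = as.numeric(q0), q1 = as.numeric(q1))
}

# initial outcome regressions from a fitted Super Learner; for the
# any-steroid group the counterfactual risk mixes the two regimens with the
# trial's randomization shares among active arms
q_init_sl <- function(fsl, rc, trials = NULL) {
  qa <- function(arms) {
    if (length(arms) == 1L)
      return(predict_risk(fsl, rc$data, arm_override = arms))
    p <- vapply(arms, function(a) predict_risk(fsl, rc$data, arm_override = a),
                numeric(nrow(rc$data)))
    if (is.null(trials)) return(rowMeans(p))
    w <- as.matrix(trials[, arms, drop = FALSE])
    rownames(w) <- trials$trial
    w <- w[as.character(rc$data$trial), , drop = FALSE]
    rs <- rowSums(w)
    rs[rs == 0] <- 1
    rowSums(p * w / rs)
  }
  cbind(q0 = qa(rc$ref), q1 = qa(rc$treated))
}

#' Targeted maximum likelihood estimate of the ATE for an arm contrast
#'
#' One-step TMLE for a binary outcome: (1) clever covariate
#' `H = A/g - (1-A)/(1-g)`; (2) a one-dimensional logistic fluctuation of
#' the initial logit-risk with `H` as covariate and the initial fit as
#' offset, solved by Newton iterations to machine precision so the
#' efficient-score equation holds; (3) updated counterfactual predictions;
#' (4) targeted means, ARR (`mean0 - mean1`, positive = fewer deaths under
#' treatment) and RR (`mean1 / mean0`); (5) variance from the efficient
#' influence curve, RR interval on the log scale by the delta method.
#'
#' @param cohort a `trial_cohort`.
#' @param contrast `c(treated, control)` arm labels; `"any_steroid"`
#'   collapses both active regimens.
#' @param outcome `"y90"` or `"y28"`.
#' @param q_init optional n x 2 matrix / data.frame with columns `q0`, `q1`
#'   of initial risk predictions under each arm (rows follow the cohort
#'   restricted to the contrast arms). Defaults to a trial-adjusted
#'   logistic regression; pass a `fitted_super_learner` via `fsl` to use
#'   ensemble predictions instead.
#' @param g a [propensity_model()], or a numeric vector/scalar of known
#'   treatment probabilities on the restricted data.
#' @param fsl optional `fitted_super_learner` for the initial fit.
#' @param gbounds truncation bounds for g (positivity guard).
#' @return A `targeted_estimate`: contrast, targeted means, `arr`, `rr`,
#'   95% CIs, two-sided Wald p-values, per-patient influence-curve values
#'   `ic`, and the fluctuation coefficient `epsilon`.
#' @export
tmle_ate <- function(cohort, contrast = c("any_steroid", "control"),
                     outcome = c("y90", "y28"), q_init = NULL, g = NULL,
                     fsl = NULL, gbounds = c(0.01, 0.99)) {
  outcome <- match.arg(outcome)
  if (is.null(g)) {
    dgp <- attr(cohort, "dgp")
    g <- propensity_model("known", trials = dgp$trials %||% NULL)
  }
  known_trials <- if (inherits(g, "propensity_model")) g$trials
  rc <- restrict_contrast(cohort, contrast, trials = known_trials)
  n <- nrow(rc$data)
  if (n == 0L || length(unique(rc$a)) < 2L)
    stop("contrast requires patients in both arms", call. = FALSE)
  y <- rc$data[[outcome]]
  graw <- propensity_scores(g, rc)
  if (any(graw <= 0 | graw >= 1))
    stop("structural positivity violation: g in {0,1}; review the contrast ",
         "and randomization design", call. = FALSE)
  gs <- pmin(pmax(graw, gbounds[1]), gbounds[2])

  if (is.null(q_init)) {
    q_init <- if (!is.null(fsl)) {
      q_init_sl(fsl, rc, trials = if (!is.numeric(g)) g$trials)
    } else q_init_glm(rc, y)
  }
  q_init <- as.matrix(q_init)
  if (nrow(q_init) == nrow(cohort) && nrow(q_init) != n)
    q_init <- q_init[rc$idx, , drop = FALSE] # rows given for the full cohort
  stopifnot(ncol(q_init) == 2L, nrow(q_init) == n)
  q0 <- clip_prob(q_init[, "q0"]); q1 <- clip_prob(q_init[, "q1"])
  qa <- ifelse(rc$a == 1L, q1, q0)

  h <- rc$a / gs - (1 - rc$a) / (1 - gs)
  off <- logit(qa)
  eps <- 0
  for (it in seq_len(100L)) {
    mu <- expit(off + eps * h)
    score <- sum(h * (y - mu))
    if (abs(score) < 1e-12 * n) break
    info <- sum(h^2 * mu * (1 - mu))
    if (info <= 0) break
    eps <- eps + score / info
  }
  q1s <- expit(logit(q1) + eps / gs)
  q0s <- expit(logit(q0) - eps / (1 - gs))
  qas <- ifelse(rc$a == 1L, q1s, q0s)

  mean1 <- mean(q1s); mean0 <- mean(q0s)
  arr <- mean0 - mean1
  rr <- mean1 / mean0

  ic1 <- rc$a / gs * (y - qas) + q1s - mean1
  ic0 <- (1 - rc$a) / (1 - gs) * (y - qas) + q0s - mean0
  ic_arr <- ic0 - ic1
  se_arr <- stats::sd(ic_arr) / sqrt(n)
  ic_lrr <- ic1 / mean1 - ic0 / mean0
  se_lrr <- stats::sd(ic_lrr) / sqrt(n)
  z <- stats::qnorm(0.975)

  structure(list(
    contrast = contrast, outcome = outcome, n = n,
    mean1 = mean1, mean0 = mean0,
    arr = arr, rr = rr,
    ci_arr = arr + c(-1, 1) * z * se_arr,
    ci_rr = exp(log(rr) + c(-1, 1) * z * se_lrr),
    se_arr = se_arr,
    p_arr = 2 * stats::pnorm(-abs(arr / se_arr)),
    p_rr = 2 * stats::pnorm(-abs(log(rr) / se_lrr)),
    ic = ic_arr, epsilon = eps
  ), class = "targeted_estimate")
}

#' @export
print.targeted_estimate <- function(x, ...) {
  cat(sprintf("TMLE %s vs %s (%s, n=%d)\n", x$contrast[1], x$contrast[2],
              x$outcome, x$n))
  cat(sprintf("  RR  %.3f (%.3f-%.3f) p=%.3g\n", x$rr, x$ci_rr[1],
              x$ci_rr[2], x$p_rr))
  cat(sprintf("  ARR %.2f%% (%.2f%%-%.2f%%) p=%.3g\n", 100 * x$arr,
              100 * x$ci_arr[1], 100 * x$ci_arr[2], x$p_arr))
  invisible(x)
}

#' Per-trial and pooled targeted estimates
#'
#' One TMLE per trial that randomized both contrast arms (strata missing an
#' arm or an outcome class are skipped with a warning, mirroring trials
#' that never randomized a given regimen), plus a pooled estimate on the
#' full restricted cohort with trial as an adjustment covariate.
#'
#' @inheritParams tmle_ate
#' @return List with `per_trial` (named list of `targeted_estimate`) and
#'   `pooled`.
#' @export
pooled_and_per_trial <- function(cohort, contrast = c("any_steroid", "control"),
                                 outcome = c("y90", "y28"), g = NULL,
                                 fsl = NULL) {
  outcome <- match.arg(outcome)
  per <- list()
  for (tr in levels(factor(cohort$trial))) {
    sub <- cohort[cohort$trial == tr, , drop = FALSE]
    attr(sub, "dgp") <- attr(cohort, "dgp")
    est <- tryCatch(
      tmle_ate(sub, contrast, outcome, g = g, fsl = fsl),
      error = function(e) {
        warning("trial '", tr, "' skipped: ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
    if (!is.null(est) && length(unique(sub[[outcome]])) < 2L) est <- NULL
    if (!is.null(est)) per[[tr]] <- est
  }
  pooled <- tmle_ate(cohort, contrast, outcome, g = g, fsl = fsl)
  list(per_trial = per, pooled = pooled)
}
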