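#' Optimize stacking weights for cross-validated AUC
#'
#' Finds a convex combination of the level-1 (out-of-fold) prediction
#' columns maximizing the AUC of the combined score. AUC is piecewise
#' constant in the weights, so the search is a fixed deterministic
#' multistart: every vertex of the simplex (i.e. each single learner), the
#' uniform weight vector, and Nelder-Mead refinements on
#' softmax-parameterized weights using a rank-smoothed AUC surrogate, all
#' scored under the exact tied-pair AUC. Ties keep the first candidate
#' found, so the returned weights are reproducible and the ensemble can
#' never score below the best single column.
#'
#' @param level1 n x L matrix of out-of-fold predictions in `[0, 1]`.
#' @param y binary outcome.
#' @return Simplex weight vector of length L.
#' @export
optimize_weights <- function(level1, y) {
  level1 <- as.matrix(level1)
  L <- ncol(level1)
  stopifnot(L >= 1L, nrow(level1) == length(y))
  if (length(unique(y)) < 2L)
    stop("outcome is constant; AUC is undefined", call. = FALSE)
  if (L == 1L) return(1)

  exact <- function(w) auc_mann_whitney(drop(level1 %*% w), y)
  softmax <- function(th) { e <- exp(th - max(th)); e / sum(e) }

  # rank-smoothed surrogate: logistic CDF of case-control score differences
  # on a capped pair subsample (differentiable enough for Nelder-Mead)
  i1 <- which(y == 1); i0 <- which(y == 0)
  max_pairs <- 50000L
  set_pairs <- expand.grid(a = i1, b = i0)
  if (nrow(set_pairs) > max_pairs)
    set_pairs <- set_pairs[seq(1L, nrow(set_pairs),
                               length.out = max_pairs), ]
  h <- max(stats::sd(level1), 0.01) / 10
  surrogate <- function(th) {
    s <- drop(level1 %*% softmax(th))
    -mean(stats::plogis((s[set_pairs$a] - s[set_pairs$b]) / h))
  }

  best_w <- NULL
  best_auc <- -Inf
  consider <- function(w) {
    a <- exact(w)
    if (a > best_auc + 1e-9) { best_auc <<- a; best_w <<- w }
  }
  for (j in seq_len(L)) consider(as.numeric(seq_len(L) == j))
  consider(rep(1 / L, L))
  starts <- c(lapply(seq_len(L), function(j) 4 * (seq_len(L) == j)),
              list(rep(0, L)))
  for (st in starts) {
    opt <- stats::optim(st, surrogate, method = "Nelder-Mead",
                        control = list(maxit = 200, reltol = 1e-8))
    consider(softmax(opt$par))
  }
  best_w
}

#' Fit the Super Learner ensemble ("optimal individual model")
#'
#' Cross-validated stacking for 90-day (or 28-day) mortality given baseline
#' covariates, missingness indicators, trial and the treatment actually
#' received. Each library member is refit per fold to build an honest
#' out-of-fold level-1 matrix; the stacking weights maximize the
#' cross-validated AUC of the convex combination; base learners are then
#' refit on the full data for prediction. A learner that fails to fit in
#' any fold is dropped with a warning and its weight mass is redistributed
#' by the optimizer over the survivors.
#'
#' @param cohort a `trial_cohort` (or compatible data.frame with `arm`,
#'   `trial`, covariates, and the outcome).
#' @param outcome `"y90"` or `"y28"`.
#' @param library named list of [learner_spec()]s.
#' @param plan a [cv_plan()]; 10 folds stratified on the outcome by default.
#' @param metalearner `"convex"` (default) stacks the library by the
#'   AUC-optimal convex combination; `"discrete"` selects the single
#'   learner with the best cross-validated AUC (one-hot weights).
#' @return A `fitted_super_learner` with elements `library`, `weights`
#'   (simplex), `base_fits`, `level1`, `cv_auc`, `feature_map`, `folds`.
#' @export
fit_super_learner <- function(cohort, outcome = c("y90", "y28"),
                              library = default_learner_library(),
                              plan = cv_plan(),
                              metalearner = c("convex", "discrete")) {
  outcome <- match.arg(outcome)
  metalearner <- match.arg(metalearner)
  stopifnot(length(library) >= 1L)
  y <- cohort[[outcome]]
  if (length(unique(y)) < 2L)
    stop("cohort must contain both outcome classes", call. = FALSE)
  fm <- feature_map(cohort)
  design <- build_design(fm, cohort)
  n <- nrow(design)
  folds <- make_folds(y, plan$n_folds, plan$seed,
                      stratified = plan$stratified)

  L <- length(library)
  level1 <- matrix(NA_real_, n, L,
                   dimnames = list(NULL, vapply(library, `[[`, "", "name")))
  ok <- rep(TRUE, L)
  for (j in seq_len(L)) {
    for (f in seq_len(plan$n_folds)) {
      tr <- folds != f
      res <- tryCatch({
        fit <- fit_learner(library[[j]], design[tr, , drop = FALSE], y[tr],
                           seed = derive_seed(plan$seed,
                                              paste(library[[j]]$name, f)))
        level1[!tr, j] <- fit$predict(design[!tr, , drop = FALSE])
        TRUE
      }, error = function(e) {
        warning("learner '", library[[j]]$name, "' failed in fold ", f,
                " (", conditionMessage(e), "); dropping it", call. = FALSE)
        FALSE
      })
      if (!res) { ok[j] <- FALSE; break }
    }
  }
  if (!any(ok)) stop("all learners failed to fit", call. = FALSE)
  library <- library[ok]
  level1 <- level1[, ok, drop = FALSE]

  weights <- if (metalearner == "discrete") {
    single <- apply(level1, 2, auc_mann_whitney, y = y)
    as.numeric(seq_along(library) == which.max(single))
  } else {
    optimize_weights(level1, y)
  }
  cv_scores <- drop(level1 %*% weights)

  base_fits <- lapply(seq_along(library), function(j)
    fit_learner(library[[j]], design, y,
                seed = derive_seed(plan$seed,
                                   paste(library[[j]]$name, "full"))))
  names(base_fits) <- names(library)

  structure(list(
    library = library,
    weights = stats::setNames(weights, names(library)),
    base_fits = base_fits,
    level1 = level1,
    cv_scores = cv_scores,
    cv_auc = auc_mann_whitney(cv_scores, y),
    outcome = outcome,
    y = y,
    folds = folds,
    feature_map = fm
  ), class = "fitted_super_learner")
}

#' Predict mortality risk from a fitted Super Learner
#'
#' Weighted combination of the full-data base-learner predictions. With
#' `arm_override`, the treatment feature is set to that arm for every
#' record — the counterfactual risk had everyone received that regimen.
#'
#' @param fsl a `fitted_super_learner`.
#' @param records patient records conforming to the feature map.
#' @param arm_override optional arm label.
#' @return Risk per record, clipped to `[1e-3, 1 - 1e-3]`.
#' @export
predict_risk <- function(fsl, records, arm_override = NULL) {
  design <- build_design(fsl$feature_map, records, arm_override)
  preds <- vapply(fsl$base_fits, function(f) f$predict(design),
                  numeric(nrow(design)))
  if (nrow(design) == 1L) preds <- matrix(preds, nrow = 1L)
  clip_prob(drop(preds %*% fsl$weights))
}

#' @export
print.fitted_super_learner <- function(x, ...) {
  cat("Super Learner (", x$outcome, "), ", length(x$library),
      " learners, CV-AUC = ", round(x$cv_auc, 3), "\n", sep = "")
  print(round(x$weights, 3))
  invisible(x)
}
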