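#' @keywords internal
#' @import stats
#' @importFrom MASS stepAIC
#' @importFrom mgcv gam
#' @importFrom glmnet glmnet cv.glmnet
#' @importFrom ranger ranger
#' @importFrom xgboost xgb.train xgb.DMatrix
#' @importFrom e1071 svm
#' @importFrom kernlab ksvm
#' @importFrom rpart rpart prune rpart.control
#' @importFrom jsonlite write_json read_json
#' @importFrom yaml read_yaml
#' @importFrom utils write.csv read.csv capture.output packageVersion
#' @importFrom graphics plot lines abline legend
"_PACKAGE"

# Arm labels used throughout: control, hydrocortisone (alone), and the
# hydrocortisone + fludrocortisone combination.
ARM_LEVELS <- c("control", "hydrocortisone", "combination")
ACTIVE_ARMS <- c("hydrocortisone", "combination")

#' Derive a reproducible substream seed
#'
#' Derives a deterministic 31-bit seed from a master seed and a stage tag so
#' that each stage of a run (covariate draw, arm draw, outcome draw, folds,
#' bootstrap, ...) consumes an independent, reproducible random substream.
#'
#' @param seed master integer seed.
#' @param tag character stage label.
#' @return An integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.double(seed) %% m
  for (k in utf8ToInt(as.character(tag))) {
    h <- (h * 31 + k) %% m
  }
  # one multiplicative scramble to decorrelate consecutive master seeds
  as.integer((h * 48271) %% m)
}

#' Clip probabilities away from 0 and 1
#'
#' Predictions are bounded to `[eps, 1 - eps]` before any logit transform;
#' this keeps the TMLE fluctuation and stacking steps numerically stable.
#'
#' @param p numeric vector of probabilities.
#' @param eps bound (default 1e-3).
#' @return Clipped vector.
#' @export
clip_prob <- function(p, eps = 1e-3) pmin(pmax(p, eps), 1 - eps)

logit <- function(p) stats::qlogis(p)
expit <- function(x) stats::plogis(x)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stratified cross-validation folds
#'
#' Assigns each observation to one of `k` folds, stratifying on a binary
#' outcome so every fold contains both classes whenever possible.
#'
#' @param y binary outcome vector.
#' @param k number of folds.
#' @param seed integer seed.
#' @param stratified stratify on `y` (default TRUE).
#' @return Integer fold id per observation.
#' @export
make_folds <- function(y, k = 10L, seed = 1L, stratified = TRUE) {
  n <- length(y)
  stopifnot(k >= 2L, k <= n)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(derive_seed(seed, "folds"))
  folds <- integer(n)
  # cycle fold ids across class-shuffled indices: folds stay balanced in
  # the outcome and every fold is nonempty for any k <= n
  ord <- if (stratified) {
    unlist(lapply(split(seq_len(n), y), sample), use.names = FALSE)
  } else sample(n)
  folds[ord] <- rep_len(seq_len(k), n)
  folds
}

#' Cross-validation plan
#'
#' @param n_folds number of folds (default 10).
#' @param stratified stratify folds on the outcome.
#' @param seed integer seed for the fold assignment.
#' @return A `cv_plan` list.
#' @export
cv_plan <- function(n_folds = 10L, stratified = TRUE, seed = 1L) {
  stopifnot(n_folds >= 2L)
  structure(list(n_folds = as.integer(n_folds), stratified = stratified,
                 seed = as.integer(seed)),
            class = "cv_plan")
}

# run expr under a local RNG state seeded by `seed`, restoring on exit
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}
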