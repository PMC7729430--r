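#' Decision tree mapping covariates to the treat / don't-treat decision
#'
#' Clinical-translation aid: labels each patient by whether their
#' estimated individual treatment effect exceeds the decision threshold
#' (`D_i > t`, i.e. treat at the chosen NWT) and fits a CART
#' classification tree of that recommendation on baseline covariates —
#' Gini impurity, cost-complexity pruning with the penalty chosen by the
#' 1-SE rule over cross-validation (20-fold by default). A regression
#' tree on `D` itself is available via `mode = "regression"`.
#'
#' @param covariates data.frame of baseline covariates (no outcomes, no
#'   treatment).
#' @param ite per-patient effect estimates `D` (e.g. the `d` column of an
#'   `ite_estimate`).
#' @param threshold decision threshold (scalar or [nwt_to_threshold()]
#'   result).
#' @param cv_folds cross-validation folds for the complexity parameter.
#' @param cp smallest complexity parameter explored while growing.
#' @param minbucket minimum leaf size.
#' @param seed seed for the internal cross-validation.
#' @param mode `"classification"` (treat/no-treat label) or
#'   `"regression"` (on `D`).
#' @return An `ite_tree`: the pruned `rpart` fit plus `threshold`, `cp`
#'   and the label table.
#' @export
fit_tree <- function(covariates, ite, threshold, cv_folds = 20L,
                     cp = 0.001, minbucket = 20L, seed = 1L,
                     mode = c("classification", "regression")) {
  mode <- match.arg(mode)
  th <- as_threshold(threshold)
  stopifnot(nrow(covariates) == length(ite))
  df <- covariates
  df$.y <- if (mode == "classification") {
    factor(ifelse(ite > th$t, "treat", "no_treat"),
           levels = c("no_treat", "treat"))
  } else ite

  if (mode == "classification" && length(unique(df$.y)) < 2L) {
    warning("all patients fall on one side of the threshold; ",
            "returning a single-leaf tree")
    fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                        control = rpart::rpart.control(cp = 1, xval = 0))
    return(structure(list(fit = fit, threshold = th, cp = 1,
                          labels = table(df$.y)), class = "ite_tree"))
  }

  fit <- with_seed(derive_seed(seed, "tree-cv"),
    rpart::rpart(.y ~ ., data = df,
                 method = if (mode == "classification") "class" else "anova",
                 parms = if (mode == "classification")
                   list(split = "gini"),
                 control = rpart::rpart.control(cp = cp, xval = cv_folds,
                                                minbucket = minbucket)))
  ct <- fit$cptable
  best <- which.min(ct[, "xerror"])
  thresh <- ct[best, "xerror"] + ct[best, "xstd"]
  chosen <- min(which(ct[, "xerror"] <= thresh))   # 1-SE rule
  pruned <- rpart::prune(fit, cp = ct[chosen, "CP"])
  structure(list(fit = pruned, threshold = th, cp = ct[chosen, "CP"],
                 cptable = ct,
                 labels = if (mode == "classification") table(df$.y)),
            class = "ite_tree")
}

#' @export
print.ite_tree <- function(x, ...) {
  cat(sprintf("Treatment-decision tree at NWT %.0f (t = %.3f), cp = %.4g\n",
              x$threshold$nwt, x$threshold$t, x$cp))
  print(x$fit)
  invisible(x)
}

#' Predict the treat / don't-treat decision from a fitted tree
#'
#' Leaf labels are deterministic: prediction equals the label of the leaf
#' the patient falls into.
#'
#' @param object an `ite_tree`.
#' @param newdata covariate data.frame.
#' @param ... unused.
#' @return Factor of decisions (classification) or numeric `D` estimates
#'   (regression).
#' @export
predict.ite_tree <- function(object, newdata, ...) {
  if (object$fit$method == "class") {
    stats::predict(object$fit, newdata, type = "class")
  } else {
    stats::predict(object$fit, newdata)
  }
}

# splits of the pruned tree as a data.frame (variable, split point)
tree_splits <- function(tree) {
  fr <- tree$fit$frame
  sp <- tree$fit$splits
  if (is.null(sp) || nrow(fr[fr$var != "<leaf>", ]) == 0L)
    return(data.frame(var = character(), index = numeric()))
  prim <- fr[fr$var != "<leaf>", , drop = FALSE]
  # first split row per internal node
  idx <- cumsum(c(1, (prim$ncompete + prim$nsurrogate +
                        1)[-nrow(prim)]))
  data.frame(var = rownames(sp)[idx], index = sp[idx, "index"])
}
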