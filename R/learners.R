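#' Base-learner specification
#'
#' One entry of the Super Learner library. Families cover the parametric
#' learners (plain and interaction logistic regression, stepwise AIC
#' selection, ridge-penalized logistic standing in for a Bayesian GLM with a
#' Gaussian prior) and the nonparametric ones (GAM, a hinge-basis lasso in
#' the spirit of first-degree MARS, gradient boosting, random forest, and
#' linear / RBF support vector machines).
#'
#' @param name unique identifier within a library.
#' @param family one of `"logistic"`, `"logistic_interactions"`,
#'   `"stepwise_aic"`, `"bayes_glm"`, `"gam"`, `"mars"`,
#'   `"gradient_boosting"`, `"random_forest"`, `"svm"`, `"kernel_svm"`.
#' @param hyper named list of family-specific settings.
#' @return A `learner_spec` object.
#' @export
learner_spec <- function(name, family = name, hyper = list()) {
  family <- match.arg(family, c(
    "logistic", "logistic_interactions", "stepwise_aic", "bayes_glm", "gam",
    "mars", "gradient_boosting", "random_forest", "svm", "kernel_svm"))
  structure(list(name = name, family = family, hyper = hyper),
            class = "learner_spec")
}

#' Default Super Learner library
#'
#' The full ten-member library: parametric and nonparametric learners wide
#' enough to approximate essentially any functional form of risk in the
#' covariates and treatment.
#'
#' @return List of [learner_spec()] objects.
#' @export
default_learner_library <- function() {
  lst <- list(
    learner_spec("logistic"),
    learner_spec("logistic_interactions"),
    learner_spec("stepwise_aic"),
    learner_spec("bayes_glm"),
    learner_spec("gam"),
    learner_spec("mars"),
    learner_spec("gradient_boosting"),
    learner_spec("random_forest"),
    learner_spec("svm"),
    learner_spec("kernel_svm")
  )
  names(lst) <- vapply(lst, `[[`, "", "name")
  lst
}

#' Reduced library for simulation studies
#'
#' A five-member subset (both logistic forms, GAM, random forest, gradient
#' boosting) that retains parametric and nonparametric coverage at a small
#' fraction of the fitting cost; used for the repeated-simulation studies.
#'
#' @return List of [learner_spec()] objects.
#' @export
fast_learner_library <- function() {
  lst <- list(
    learner_spec("logistic"),
    learner_spec("logistic_interactions"),
    learner_spec("gam"),
    learner_spec("random_forest", hyper = list(num.trees = 300)),
    learner_spec("gradient_boosting", hyper = list(nrounds = 120))
  )
  names(lst) <- vapply(lst, `[[`, "", "name")
  lst
}

# columns entering treatment x covariate interactions for parametric learners
interaction_vars <- function(design, hyper) {
  vars <- hyper$interactions %||% c("saps2", "cortisol_increment")
  intersect(vars, names(design))
}

# model matrix shared by the penalized learners; factor levels come from the
# design frame so train/test encodings agree
design_matrix <- function(design, with_interactions = FALSE, hyper = list()) {
  f <- ~.
  if (with_interactions && "arm" %in% names(design)) {
    iv <- interaction_vars(design, hyper)
    if (length(iv))
      f <- stats::as.formula(paste("~ . +",
        paste(paste0("arm:", iv), collapse = " + ")))
  }
  stats::model.matrix(f, data = design)[, -1, drop = FALSE]
}

# degree-1 hinge basis at inner quantiles of each numeric column
hinge_basis <- function(design, knots = NULL) {
  num <- names(design)[vapply(design, is.numeric, NA)]
  num <- num[vapply(design[num], function(x) length(unique(x)) > 5, NA)]
  if (is.null(knots)) {
    knots <- lapply(design[num], stats::quantile,
                    probs = c(0.25, 0.5, 0.75), names = FALSE)
    names(knots) <- num
  }
  cols <- list()
  for (nm in names(knots)) {
    x <- design[[nm]]
    for (k in knots[[nm]]) {
      cols[[paste0(nm, "_hp", signif(k, 4))]] <- pmax(x - k, 0)
      cols[[paste0(nm, "_hm", signif(k, 4))]] <- pmax(k - x, 0)
    }
  }
  list(mat = if (length(cols)) do.call(cbind, cols) else NULL, knots = knots)
}

glm_formula <- function(design, interactions = FALSE, hyper = list()) {
  if (!interactions) return(y ~ .)
  if ("arm" %in% names(design)) {
    iv <- interaction_vars(design, hyper)
    if (length(iv))
      return(stats::as.formula(paste("y ~ . +",
        paste(paste0("arm:", iv), collapse = " + "))))
  }
  y ~ .^2
}

#' Fit one base learner
#'
#' Fits a single library member on a design frame and binary outcome and
#' returns an object whose `$predict(newdesign)` closure yields clipped
#' probabilities. All stochastic learners are seeded for reproducibility.
#'
#' @param spec a [learner_spec()].
#' @param design predictor data.frame from [build_design()].
#' @param y binary outcome vector.
#' @param seed integer seed.
#' @return A `fitted_learner` with elements `spec` and `predict`.
#' @export
fit_learner <- function(spec, design, y, seed = 1L) {
  df <- cbind(design, y = y)
  pred <- switch(spec$family,
    logistic = {
      fit <- stats::glm(y ~ ., binomial(), data = df)
      function(nd) stats::predict(fit, nd, type = "response")
    },
    logistic_interactions = {
      fit <- stats::glm(glm_formula(design, TRUE, spec$hyper), binomial(),
                        data = df)
      function(nd) stats::predict(fit, nd, type = "response")
    },
    stepwise_aic = {
      full <- stats::glm(y ~ ., binomial(), data = df)
      fit <- MASS::stepAIC(full, direction = "both", trace = 0)
      function(nd) stats::predict(fit, nd, type = "response")
    },
    bayes_glm = {
      # ridge logistic = posterior mode under a Gaussian coefficient prior
      x <- design_matrix(design, TRUE, spec$hyper)
      lam <- spec$hyper$lambda %||% 2 / length(y)
      fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                            lambda = sort(c(lam, lam * c(100, 10, 0.1)),
                                          decreasing = TRUE))
      function(nd) as.numeric(stats::predict(
        fit, design_matrix(nd, TRUE, spec$hyper), s = lam,
        type = "response"))
    },
    gam = {
      num <- names(design)[vapply(design, is.numeric, NA)]
      smooth <- num[vapply(design[num],
                           function(x) length(unique(x)) >= 10, NA)]
      lin <- setdiff(names(design), smooth)
      rhs <- c(
        if (length(smooth))
          paste0("s(", smooth, ", k = ",
                 pmin(8, vapply(design[smooth],
                                function(x) length(unique(x)), 0L) - 2), ")"),
        lin)
      fit <- mgcv::gam(stats::as.formula(
        paste("y ~", paste(rhs, collapse = " + "))),
        family = binomial(), data = df, method = "REML")
      function(nd) as.numeric(stats::predict(fit, nd, type = "response"))
    },
    mars = {
      # first-degree MARS flavour: hinge expansion + lasso selection
      x0 <- design_matrix(design, TRUE, spec$hyper)
      hb <- hinge_basis(design)
      x <- cbind(x0, hb$mat)
      set.seed(seed)
      fit <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = 1,
                               nfolds = 5)
      function(nd) {
        xn <- cbind(design_matrix(nd, TRUE, spec$hyper),
                    hinge_basis(nd, hb$knots)$mat)
        as.numeric(stats::predict(fit, xn, s = "lambda.min",
                                  type = "response"))
      }
    },
    gradient_boosting = {
      x <- design_matrix(design)
      set.seed(seed)
      dtrain <- xgboost::xgb.DMatrix(x, label = y)
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      eta = spec$hyper$eta %||% 0.1,
                      max_depth = spec$hyper$max_depth %||% 3,
                      subsample = spec$hyper$subsample %||% 0.8,
                      colsample_bytree = 0.8, nthread = 1),
        data = dtrain, nrounds = spec$hyper$nrounds %||% 200, verbose = 0)
      function(nd) as.numeric(stats::predict(
        fit, xgboost::xgb.DMatrix(design_matrix(nd))))
    },
    random_forest = {
      fit <- ranger::ranger(
        y = factor(y), x = design, probability = TRUE,
        num.trees = spec$hyper$num.trees %||% 500,
        min.node.size = spec$hyper$min.node.size %||% 10,
        respect.unordered.factors = "order", seed = seed,
        num.threads = 1)
      function(nd) stats::predict(fit, nd,
                                  num.threads = 1)$predictions[, "1"]
    },
    svm = {
      set.seed(seed)
      fit <- e1071::svm(x = design_matrix(design), y = factor(y),
                        kernel = "linear", cost = spec$hyper$cost %||% 1,
                        probability = TRUE)
      function(nd) {
        p <- stats::predict(fit, design_matrix(nd), probability = TRUE)
        attr(p, "probabilities")[, "1"]
      }
    },
    kernel_svm = {
      set.seed(seed)
      fit <- kernlab::ksvm(design_matrix(design), factor(y),
                           kernel = "rbfdot", C = spec$hyper$C %||% 1,
                           prob.model = TRUE)
      function(nd) kernlab::predict(fit, design_matrix(nd),
                                    type = "probabilities")[, "1"]
    }
  )
  structure(list(spec = spec,
                 predict = function(nd) clip_prob(as.numeric(pred(nd)))),
            class = "fitted_learner")
}
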