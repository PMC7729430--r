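#' Feature map: covariate-to-design encoding for the risk models
#'
#' Captures everything needed to turn patient records into a model design
#' reproducibly: which columns are covariates vs. missingness indicators,
#' factor level sets, and the training medians/modes used to impute missing
#' values (the binary indicators stay in the design so informative
#' missingness can be picked up by the learners).
#'
#' @param data a `trial_cohort` or plain data.frame of predictors.
#' @param outcome outcome column(s) to exclude from the predictor set.
#' @return A `feature_map` object.
#' @export
feature_map <- function(data, outcome = c("y90", "y28")) {
  drop <- c("id", outcome, grep("^risk_", names(data), value = TRUE))
  cols <- setdiff(names(data), drop)
  miss_cols <- grep("^miss_", cols, value = TRUE)
  covs <- setdiff(cols, c(miss_cols, "arm", "trial"))
  info <- lapply(covs, function(nm) {
    x <- data[[nm]]
    if (is.factor(x) || is.character(x)) {
      x <- as.factor(x)
      tab <- table(x)
      list(kind = "factor", levels = levels(x),
           impute = names(tab)[which.max(tab)])
    } else {
      list(kind = "numeric",
           impute = stats::median(as.numeric(x), na.rm = TRUE))
    }
  })
  names(info) <- covs
  structure(list(
    covariates = info,
    miss_cols = miss_cols,
    has_arm = "arm" %in% cols,
    has_trial = "trial" %in% cols,
    trial_levels = if ("trial" %in% cols) levels(as.factor(data$trial)),
    arm_levels = if ("arm" %in% cols) levels(as.factor(data$arm)) else ARM_LEVELS
  ), class = "feature_map")
}

#' Build a model design frame from patient records
#'
#' Imputes missing covariate values with the training median/mode recorded
#' in the feature map, keeps missingness indicators as numeric 0/1 columns,
#' and optionally overrides the treatment column for counterfactual
#' prediction (every record is set to `arm_override`).
#'
#' @param fm a [feature_map()].
#' @param data records to encode.
#' @param arm_override optional arm label; if given, the treatment feature
#'   is set to this arm for every record.
#' @return A data.frame of predictors.
#' @export
build_design <- function(fm, data, arm_override = NULL) {
  out <- list()
  for (nm in names(fm$covariates)) {
    ci <- fm$covariates[[nm]]
    if (!nm %in% names(data))
      stop("records lack covariate '", nm, "'", call. = FALSE)
    x <- data[[nm]]
    if (ci$kind == "factor") {
      x <- as.character(x)
      bad <- setdiff(unique(x[!is.na(x)]), ci$levels)
      if (length(bad))
        stop("unknown level(s) ", paste(bad, collapse = ", "),
             " in column '", nm, "'", call. = FALSE)
      x[is.na(x)] <- ci$impute
      out[[nm]] <- factor(x, levels = ci$levels)
    } else {
      x <- as.numeric(x)
      x[is.na(x)] <- ci$impute
      out[[nm]] <- x
    }
  }
  for (nm in fm$miss_cols) {
    out[[nm]] <- if (nm %in% names(data)) as.numeric(data[[nm]])
                 else numeric(nrow(data))
  }
  if (fm$has_trial) {
    out$trial <- factor(as.character(data$trial), levels = fm$trial_levels)
    if (anyNA(out$trial)) stop("unknown trial label", call. = FALSE)
  }
  if (fm$has_arm) {
    a <- if (!is.null(arm_override)) {
      if (!arm_override %in% fm$arm_levels)
        stop("unknown arm '", arm_override, "'", call. = FALSE)
      rep(arm_override, nrow(data))
    } else as.character(data$arm)
    out$arm <- factor(a, levels = fm$arm_levels)
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}
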