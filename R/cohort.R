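#' Generate a synthetic multi-trial septic-shock cohort
#'
#' Draws `n` patients: trial membership proportional to the configured trial
#' sizes (largest-remainder apportionment, deterministic), baseline
#' covariates from their marginal specifications, treatment arm from the
#' per-trial randomization probabilities, and 90-day / 28-day mortality from
#' the per-arm true risks. The returned cohort carries each patient's true
#' counterfactual risk under every arm (`risk_<arm>` columns) so simulation
#' oracles can be computed downstream; real data would not have these.
#'
#' @param n cohort size (>= 1).
#' @param specs covariate dictionary, a named list of [covariate_spec()].
#' @param dgp [dgp_params()] object.
#' @param seed master seed (defaults to `dgp$seed`); the same
#'   `(specs, dgp, n, seed)` always yields a byte-identical cohort.
#' @return A `trial_cohort` data.frame: `id`, `trial`, `arm`, `y28`, `y90`,
#'   one column per covariate, `miss_<covariate>` indicators (all 0 until
#'   [apply_missingness()]), and `risk_<arm>` true-risk columns.
#' @export
generate_cohort <- function(n, specs = default_covariate_specs(),
                            dgp = default_dgp(), seed = dgp$seed) {
  stopifnot(n >= 1)
  n <- as.integer(n)
  for (s in specs) {
    if (!inherits(s, "covariate_spec"))
      stop("specs must be a list of covariate_spec objects", call. = FALSE)
  }

  # largest-remainder apportionment of n over trials
  share <- dgp$trials$size / sum(dgp$trials$size) * n
  base <- floor(share)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(share - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  trial <- factor(rep(dgp$trials$trial, base), levels = dgp$trials$trial)

  cov_df <- with_seed(derive_seed(seed, "covariates"),
    as.data.frame(lapply(specs, draw_covariate, n = n),
                  stringsAsFactors = FALSE))
  names(cov_df) <- names(specs)

  pmat <- as.matrix(dgp$trials[, ARM_LEVELS])
  rownames(pmat) <- dgp$trials$trial
  arm <- with_seed(derive_seed(seed, "arms"), {
    idx <- vapply(as.character(trial), function(tr)
      sample.int(3L, 1L, prob = pmat[tr, ]), 1L)
    factor(ARM_LEVELS[idx], levels = ARM_LEVELS)
  })

  data <- cbind(cov_df, trial = trial)
  risks <- arm_risks(dgp, data)
  p_assigned <- risks[cbind(seq_len(n), as.integer(arm))]

  ef <- dgp$day28$early_fraction
  out90 <- with_seed(derive_seed(seed, "outcomes"), {
    y90 <- stats::rbinom(n, 1L, p_assigned)
    early <- stats::rbinom(n, 1L, ef)
    list(y90 = y90, y28 = as.integer(y90 & early))
  })

  miss <- as.data.frame(matrix(0L, n, length(specs)),
                        stringsAsFactors = FALSE)
  names(miss) <- paste0("miss_", names(specs))

  cohort <- cbind(
    data.frame(id = seq_len(n), trial = trial, arm = arm,
               y28 = out90$y28, y90 = out90$y90),
    cov_df, miss,
    as.data.frame(risks)[, ARM_LEVELS] |>
      stats::setNames(paste0("risk_", ARM_LEVELS))
  )
  structure(cohort,
            class = c("trial_cohort", "data.frame"),
            specs = specs, dgp = dgp, seed = as.integer(seed))
}

#' Blank covariate values according to the missingness mechanisms
#'
#' Applies each configured mechanism: covariate `j` is set to `NA` with
#' probability `plogis(intercept + slope * (value - center))`, and the
#' matching `miss_j` indicator is set to 1. A nonzero slope makes the
#' mechanism depend on the (about-to-be-hidden) value itself — missing not
#' at random. Outcomes, arm and trial are never blanked.
#'
#' @param cohort a complete `trial_cohort`.
#' @param dgp `dgp_params` carrying the mechanisms.
#' @param seed seed for the missingness draw.
#' @return The cohort with `NA`s and updated indicators.
#' @export
apply_missingness <- function(cohort, dgp = attr(cohort, "dgp"),
                              seed = attr(cohort, "seed") %||% dgp$seed) {
  mech <- dgp$missingness
  if (length(mech) == 0L) return(cohort)
  unknown <- setdiff(names(mech), names(cohort))
  if (length(unknown))
    stop("missingness mechanism references unknown covariate(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  with_seed(derive_seed(seed, "missingness"), {
    for (nm in names(mech)) {
      m <- mech[[nm]]
      x <- as.numeric(cohort[[nm]])
      pm <- expit(m$intercept + (m$slope %||% 0) * (x - (m$center %||% 0)))
      hit <- stats::rbinom(nrow(cohort), 1L, pm) == 1L
      cohort[[nm]][hit] <- NA
      cohort[[paste0("miss_", nm)]] <- as.integer(hit)
    }
  })
  cohort
}

#' True per-patient treatment effect (simulation oracle)
#'
#' Returns the true individual treatment effect — control-arm risk minus
#' arm risk, per active regimen — carried by a synthetic cohort. Positive
#' values mean the regimen lowers that patient's 90-day mortality risk.
#'
#' @param cohort a `trial_cohort` carrying `risk_<arm>` columns.
#' @param arms regimens to difference against control.
#' @return data.frame with one ARR column per regimen plus `d` (the maximum
#'   over regimens) and `best` (the regimen attaining it; ties go to
#'   hydrocortisone alone, the lower-exposure regimen).
#' @export
true_ite <- function(cohort, arms = ACTIVE_ARMS) {
  need <- paste0("risk_", c("control", arms))
  if (!all(need %in% names(cohort)))
    stop("cohort lacks true counterfactual risks (risk_* columns); ",
         "true_ite is only defined for synthetic cohorts", call. = FALSE)
  out <- data.frame(id = cohort$id %||% seq_len(nrow(cohort)))
  for (a in arms) out[[a]] <- cohort$risk_control - cohort[[paste0("risk_", a)]]
  m <- as.matrix(out[, arms, drop = FALSE])
  out$d <- apply(m, 1, max)
  out$best <- arms[max.col(m, ties.method = "first")]
  out
}

#' Write / read a cohort as CSV with a sidecar data dictionary
#'
#' One row per patient; missing values are empty fields. A JSON dictionary
#' (`<path>.json`) records column types, units and factor levels so a
#' round-trip preserves factor encodings.
#'
#' @param cohort a `trial_cohort`.
#' @param path CSV destination.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "")
  dict <- lapply(names(cohort), function(nm) {
    x <- cohort[[nm]]
    list(column = nm,
         type = if (is.factor(x)) "categorical"
                else if (all(x %in% c(0L, 1L, NA))) "binary" else "numeric",
         levels = if (is.factor(x)) levels(x) else NULL)
  })
  jsonlite::write_json(dict, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  dict_path <- paste0(path, ".json")
  if (file.exists(dict_path)) {
    dict <- jsonlite::read_json(dict_path)
    for (d in dict) {
      if (identical(d$type, "categorical") && d$column %in% names(df))
        df[[d$column]] <- factor(df[[d$column]], levels = unlist(d$levels))
    }
  }
  structure(df, class = c("trial_cohort", "data.frame"))
}
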