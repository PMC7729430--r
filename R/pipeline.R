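#' Run configuration for the full analysis
#'
#' Validated bundle of settings for [run_full_analysis()]. Either build it
#' programmatically or load a YAML file with the same field names.
#'
#' @param out_dir output directory.
#' @param n cohort size (ignored when `cohort_csv` is given).
#' @param seed master seed; per-stage substreams are derived from it.
#' @param outcome `"y90"` or `"y28"`.
#' @param cohort_csv optional path to an existing cohort CSV (skips
#'   simulation).
#' @param library Super Learner library (list of [learner_spec()] or a
#'   character vector of family names).
#' @param n_folds cross-validation folds for the ensemble.
#' @param nwt_grid number-willing-to-treat grid.
#' @param bootstrap_B bootstrap replicates for the net-benefit bands.
#' @param tree_nwt NWT at which the decision tree is built.
#' @param regimen_rr empirical relative risks for the severity strategy.
#' @param holdout optional list `list(n, seed, mortality_shift)` describing
#'   a held-out cohort with a log-odds mortality shift for external-style
#'   validation.
#' @return A `run_config` object.
#' @export
run_config <- function(out_dir, n = 2548L, seed = 1L, outcome = "y90",
                       cohort_csv = NULL, library = fast_learner_library(),
                       n_folds = 10L, nwt_grid = 2:100, bootstrap_B = 500L,
                       tree_nwt = 50, regimen_rr = default_regimen_rr(),
                       holdout = NULL) {
  stopifnot(is.character(out_dir), length(out_dir) == 1L)
  outcome <- match.arg(outcome, c("y90", "y28"))
  if (is.character(library))
    library <- stats::setNames(lapply(library, learner_spec), library)
  stopifnot(n >= 1, n_folds >= 2, all(nwt_grid > 0), tree_nwt > 0)
  structure(list(out_dir = out_dir, n = as.integer(n),
                 seed = as.integer(seed), outcome = outcome,
                 cohort_csv = cohort_csv, library = library,
                 n_folds = as.integer(n_folds), nwt_grid = nwt_grid,
                 bootstrap_B = as.integer(bootstrap_B), tree_nwt = tree_nwt,
                 regimen_rr = regimen_rr, holdout = holdout),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file with `run_config` fields.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

#' Run the full individual-treatment-effect analysis
#'
#' End-to-end orchestration in the order of the analysis: simulate (or
#' load) the cohort and apply missingness; targeted estimates of the ATE
#' (per trial and pooled) for every arm contrast; fit the optimal
#' individual model; evaluate its discrimination and calibration
#' (internally, and on a held-out shifted-mortality cohort when
#' configured); estimate per-patient effects by both methods; net-benefit
#' curves for all strategies; and the decision tree. All outputs are
#' written under `config$out_dir` (CSV for tables, JSON for structured
#' results) together with a manifest recording versions, seeds and file
#' checksums — the manifest is byte-identical across reruns of the same
#' configuration.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the in-memory results
#'   (`cohort`, `ate`, `fsl`, `evaluation`, `ite`, `net_benefit`, `tree`,
#'   `manifest`).
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  cohort <- stage("cohort", {
    if (!is.null(config$cohort_csv)) {
      read_cohort(config$cohort_csv)
    } else {
      dgp <- default_dgp(seed = config$seed)
      apply_missingness(generate_cohort(config$n, dgp = dgp))
    }
  })
  write_cohort(cohort, out("cohort.csv"))

  contrasts <- list(c("any_steroid", "control"),
                    c("hydrocortisone", "control"),
                    c("combination", "control"),
                    c("hydrocortisone", "combination"))
  ate <- stage("ate", {
    res <- lapply(contrasts, function(ct)
      pooled_and_per_trial(cohort, ct, outcome = config$outcome))
    names(res) <- vapply(contrasts, paste, "", collapse = "_vs_")
    res
  })
  ate_json <- lapply(ate, function(x) {
    fmt <- function(e) list(n = e$n, rr = e$rr, rr_ci = e$ci_rr,
                            p_rr = e$p_rr, arr = e$arr, arr_ci = e$ci_arr,
                            p_arr = e$p_arr)
    c(lapply(x$per_trial, fmt), list(pooled = fmt(x$pooled)))
  })
  jsonlite::write_json(ate_json, out("ate.json"), auto_unbox = TRUE,
                       digits = NA)

  fsl <- stage("super_learner",
    fit_super_learner(cohort, outcome = config$outcome,
                      library = config$library,
                      plan = cv_plan(config$n_folds,
                                     seed = derive_seed(config$seed, "sl"))))

  evaluation <- stage("evaluation", {
    y <- cohort[[config$outcome]]
    internal <- evaluation_report(fsl$cv_scores, y)
    saps_scores <- saps2_baseline_risk(
      ifelse(is.na(cohort$saps2),
             stats::median(cohort$saps2, na.rm = TRUE), cohort$saps2))
    saps <- evaluation_report(saps_scores, y)
    ext <- NULL
    if (!is.null(config$holdout)) {
      hd <- config$holdout
      dgp2 <- default_dgp(seed = hd$seed %||% (config$seed + 1L))
      dgp2$baseline$intercept <- dgp2$baseline$intercept +
        (hd$mortality_shift %||% 0.5)
      held <- apply_missingness(generate_cohort(hd$n %||% 300L, dgp = dgp2))
      ext <- evaluation_report(predict_risk(fsl, held),
                               held[[config$outcome]])
    }
    list(optimal_model = internal, saps2 = saps, external = ext)
  })
  eval_json <- lapply(evaluation, function(e) {
    if (is.null(e)) return(NULL)
    list(auc = e$auc, auc_ci = e$auc_ci, brier = e$brier, n = e$n)
  })
  jsonlite::write_json(eval_json, out("evaluation.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")

  ite <- stage("ite", {
    list(optimal = ite_optimal(fsl, cohort),
         saps2 = ite_saps2_cohort(cohort, rr = config$regimen_rr))
  })
  utils::write.csv(ite$optimal, out("ite_optimal.csv"), row.names = FALSE)
  utils::write.csv(ite$saps2, out("ite_saps2.csv"), row.names = FALSE)

  nb <- stage("net_benefit", {
    best <- apply(as.matrix(
      ite$optimal[, ACTIVE_ARMS, drop = FALSE]), 1, max)
    strategies <- list(
      treat_none = list(type = "treat_none"),
      treat_all_hydrocortisone = list(
        type = "treat_all", d = ite$optimal$hydrocortisone),
      treat_all_combination = list(
        type = "treat_all", d = ite$optimal$combination),
      rule_saps2 = list(type = "rule", d = ite$saps2$d),
      rule_optimal = list(type = "rule", d = best))
    net_benefit_curves(strategies, nwt_grid = config$nwt_grid,
                       bootstrap_B = config$bootstrap_B,
                       seed = derive_seed(config$seed, "nb"),
                       strata = cohort$trial)
  })
  utils::write.csv(nb, out("net_benefit.csv"), row.names = FALSE)

  tree <- stage("tree", {
    covs <- cohort[, intersect(
      c("age", "male", "admission", "saps2", "sofa", "infection_site",
        "hospital_acquired", "pathogen", "cortisol_baseline",
        "cortisol_increment", "lactate", "norepinephrine"),
      names(cohort)), drop = FALSE]
    fit_tree(covs, ite$optimal$d, nwt_to_threshold(config$tree_nwt),
             seed = derive_seed(config$seed, "tree"))
  })
  capture <- utils::capture.output(print(tree))
  writeLines(capture, out("tree.txt"))

  files <- c("cohort.csv", "cohort.csv.json", "ate.json", "evaluation.json",
             "ite_optimal.csv", "ite_saps2.csv", "net_benefit.csv",
             "tree.txt")
  manifest <- list(
    package = "steroidite",
    version = as.character(utils::packageVersion("steroidite")),
    seed = config$seed, n = nrow(cohort), outcome = config$outcome,
    learners = names(config$library),
    n_folds = config$n_folds, bootstrap_B = config$bootstrap_B,
    files = lapply(stats::setNames(files, files), function(f)
      unname(tools::md5sum(out(f)))))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)

  invisible(list(cohort = cohort, ate = ate, fsl = fsl,
                 evaluation = evaluation, ite = ite, net_benefit = nb,
                 tree = tree, manifest = manifest))
}
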