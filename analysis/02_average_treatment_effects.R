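#!/usr/bin/env Rscript
# Stage 2 — targeted (TMLE) average treatment effects.
#
# Per-trial and pooled ATE for every arm contrast, on 90-day and 28-day
# mortality, with the known randomization probabilities as the propensity.
# Trials that never randomized one side of a contrast are excluded from it
# (the COIITSS-like trial has no placebo arm). Output mirrors the usual
# RR / ARR table layout.

suppressPackageStartupMessages(library(steroidite))

cohort <- read_cohort("results/cohort.csv")
attr(cohort, "dgp") <- default_dgp(seed = 20260929L)

contrasts <- list(c("any_steroid", "control"),
                  c("hydrocortisone", "control"),
                  c("combination", "control"),
                  c("hydrocortisone", "combination"))

for (outcome in c("y90", "y28")) {
  cat("\n==", outcome, "mortality ==\n")
  all_res <- list()
  for (ct in contrasts) {
    res <- suppressMessages(suppressWarnings(
      pooled_and_per_trial(cohort, ct, outcome = outcome)))
    key <- paste(ct, collapse = "_vs_")
    all_res[[key]] <- res
    p <- res$pooled
    cat(sprintf("%-32s RR %.2f (%.2f-%.2f)  ARR %5.2f%% (%.2f to %.2f)  n=%d\n",
                key, p$rr, p$ci_rr[1], p$ci_rr[2], 100 * p$arr,
                100 * p$ci_arr[1], 100 * p$ci_arr[2], p$n))
    for (nm in names(res$per_trial)) {
      e <- res$per_trial[[nm]]
      cat(sprintf("    %-10s RR %.2f (%.2f-%.2f)  ARR %5.2f%%  n=%d\n",
                  nm, e$rr, e$ci_rr[1], e$ci_rr[2], 100 * e$arr, e$n))
    }
  }
  out <- lapply(all_res, function(x) {
    fmt <- function(e) list(n = e$n, rr = e$rr, rr_ci = e$ci_rr, p_rr = e$p_rr,
                            arr = e$arr, arr_ci = e$ci_arr, p_arr = e$p_arr)
    c(lapply(x$per_trial, fmt), list(pooled = fmt(x$pooled)))
  })
  jsonlite::write_json(out, paste0("results/ate_", outcome, ".json"),
                       auto_unbox = TRUE, digits = NA)
}
cat("\nWritten: results/ate_y90.json, results/ate_y28.json\n")
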