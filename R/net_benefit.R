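#' Convert between number willing to treat and decision threshold
#'
#' The number willing to treat (NWT) is the maximum acceptable number of
#' patients treated to prevent one event; it is the inverse of the decision
#' threshold `T` on the individual risk-difference scale (`NWT = 1/T`, so a
#' threshold of 10% corresponds to an NWT of 10).
#'
#' @param nwt positive number willing to treat.
#' @return A `threshold` list with components `t` and `nwt` (`t * nwt = 1`).
#' @export
nwt_to_threshold <- function(nwt) {
  if (!is.numeric(nwt) || length(nwt) != 1L || !is.finite(nwt) || nwt <= 0)
    stop("nwt must be a positive number", call. = FALSE)
  structure(list(t = 1 / nwt, nwt = nwt), class = "threshold")
}

#' @rdname nwt_to_threshold
#' @param t decision threshold in (0, 1].
#' @export
threshold_to_nwt <- function(t) {
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t <= 0 || t > 1)
    stop("t must lie in (0, 1]", call. = FALSE)
  structure(list(t = t, nwt = 1 / t), class = "threshold")
}

as_threshold <- function(x) {
  if (inherits(x, "threshold")) x else threshold_to_nwt(x)
}

#' Net benefit of treating everybody
#'
#' For the treat-all strategy the event-rate decrease is the average
#' treatment effect and everyone is treated, so
#' `net benefit = ATE - 1 * T`.
#'
#' @param ate_arr absolute risk reduction of the strategy's regimen.
#' @param t decision threshold (scalar in `[0, 1]` or a `threshold`).
#' @return Net benefit (scalar).
#' @export
net_benefit_treat_all <- function(ate_arr, t) {
  t <- if (inherits(t, "threshold")) t$t else t
  stopifnot(is.finite(ate_arr), is.finite(t))
  ate_arr - t
}

#' Net benefit of a rule-based strategy
#'
#' Treatment is initiated in patient `i` iff their estimated individual
#' effect `D_i` exceeds the threshold `t`. The event-rate decrease is the
#' population average of `D_i` over the treated (i.e. `mean(D * (D > t))`
#' over all patients) and the net benefit subtracts the treated fraction
#' times the threshold:
#' `NB = mean(D * 1{D > t}) - mean(1{D > t}) * t`.
#' This is the reading of the rule formula under which it agrees with the
#' decrease-in-event-rate definition and collapses to the treat-all and
#' treat-none references at the grid ends.
#'
#' @param ite_values per-patient estimated treatment effects `D`.
#' @param t decision threshold.
#' @return List with `net_benefit`, `treated_fraction`,
#'   `event_rate_decrease`.
#' @export
net_benefit_rule <- function(ite_values, t) {
  if (length(ite_values) == 0L)
    stop("ite_values must be nonempty", call. = FALSE)
  t <- if (inherits(t, "threshold")) t$t else t
  treat <- ite_values > t
  dec <- mean(ite_values * treat)
  list(net_benefit = dec - mean(treat) * t,
       treated_fraction = mean(treat),
       event_rate_decrease = dec)
}

#' Oracle net benefit from true counterfactual risks
#'
#' Simulation ground truth: with the synthetic cohort's true per-arm event
#' probabilities (the expected potential outcomes), a treatment rule's
#' event-rate decrease is the mean over treated patients' true risk
#' reductions under the regimen the rule assigns, taken over the whole
#' cohort. Treating no one gives exactly zero. Under this definition the
#' threshold rule "treat iff true `D_i > t`" is optimal over all
#' covariate-measurable rules.
#'
#' @param cohort synthetic `trial_cohort` carrying `risk_<arm>` columns.
#' @param treat logical vector: whom the rule treats.
#' @param t decision threshold.
#' @param regimen single regimen label, or a character vector per patient
#'   (e.g. each patient's best regimen).
#' @return List with `net_benefit`, `treated_fraction`,
#'   `event_rate_decrease`.
#' @export
oracle_net_benefit <- function(cohort, treat, t,
                               regimen = "hydrocortisone") {
  need <- paste0("risk_", unique(c("control", regimen)))
  if (!all(need %in% names(cohort)))
    stop("cohort lacks true counterfactual risks; the oracle net benefit ",
         "is only defined for synthetic cohorts", call. = FALSE)
  t <- if (inherits(t, "threshold")) t$t else t
  stopifnot(length(treat) == nrow(cohort))
  regimen <- rep_len(regimen, nrow(cohort))
  r1 <- vapply(seq_len(nrow(cohort)),
               function(i) cohort[[paste0("risk_", regimen[i])]][i], 0)
  dec <- mean((cohort$risk_control - r1) * treat)
  list(net_benefit = dec - mean(treat) * t,
       treated_fraction = mean(treat),
       event_rate_decrease = dec)
}

#' Net-benefit curves over an NWT grid, with bootstrap bands
#'
#' Computes, for each strategy, the net benefit and treated fraction at
#' every number-willing-to-treat value, with percentile bootstrap
#' confidence bands over patient-level resampling (stratified by trial
#' when labels are supplied). Strategies are described by a type and the
#' per-patient effect estimates they act on:
#' * `treat_all` — everyone gets the regimen; NB = mean(D) - t,
#' * `rule` — treat iff `D_i > t`,
#' * `treat_none` — reference, identically zero.
#'
#' @param strategies named list; each element is
#'   `list(type = "treat_all"|"rule"|"treat_none", d = <numeric per patient>)`
#'   (`d` unused for `treat_none`).
#' @param nwt_grid numbers willing to treat (default 2:100).
#' @param bootstrap_B bootstrap replicates (default 500); below 2 the
#'   bands are omitted with a warning.
#' @param seed bootstrap seed.
#' @param strata optional per-patient stratum labels (trial) for
#'   stratified resampling.
#' @return `net_benefit_curves` data.frame: `strategy`, `nwt`, `t`,
#'   `net_benefit`, `treated_fraction`, `ci_lo`, `ci_hi`.
#' @export
net_benefit_curves <- function(strategies, nwt_grid = 2:100,
                               bootstrap_B = 500L, seed = 1L,
                               strata = NULL) {
  stopifnot(length(nwt_grid) >= 1L, all(nwt_grid > 0))
  ts <- 1 / nwt_grid
  one <- function(st, idx) {
    vapply(ts, function(t) {
      switch(st$type,
        treat_none = c(0, 0),
        treat_all = c(mean(st$d[idx]) - t, 1),
        rule = {
          r <- net_benefit_rule(st$d[idx], t)
          c(r$net_benefit, r$treated_fraction)
        },
        stop("unknown strategy type '", st$type, "'", call. = FALSE))
    }, numeric(2))
  }
  n <- max(vapply(strategies,
                  function(s) length(s$d %||% numeric()), 0L), 1L)
  idx0 <- seq_len(n)
  do_boot <- bootstrap_B >= 2L
  if (!do_boot) warning("bootstrap_B < 2; confidence bands omitted")

  # resampling is done from stratum-sorted values so the bands depend only
  # on the multiset of estimates per stratum, not on patient ordering
  groups <- if (is.null(strata)) list(idx0) else
    split(idx0, as.character(strata))
  boot_draws <- if (do_boot) with_seed(derive_seed(seed, "nb-bootstrap"), {
    lapply(seq_len(bootstrap_B), function(b)
      lapply(groups, function(gi)
        sample.int(length(gi), length(gi), replace = TRUE)))
  })

  out <- lapply(names(strategies), function(nm) {
    st <- strategies[[nm]]
    est <- one(st, idx0)
    ci_lo <- ci_hi <- rep(NA_real_, length(ts))
    if (do_boot && st$type != "treat_none") {
      sorted <- lapply(groups, function(gi) sort(st$d[gi]))
      st_b <- st
      bmat <- vapply(boot_draws, function(dr) {
        st_b$d <- unlist(mapply(function(v, i) v[i], sorted, dr,
                                SIMPLIFY = FALSE), use.names = FALSE)
        one(st_b, seq_along(st_b$d))[1, ]
      }, numeric(length(ts)))
      if (is.null(dim(bmat))) bmat <- matrix(bmat, nrow = length(ts))
      qs <- apply(bmat, 1, stats::quantile, probs = c(0.025, 0.975),
                  names = FALSE)
      ci_lo <- qs[1, ]; ci_hi <- qs[2, ]
    } else if (do_boot) {
      ci_lo <- ci_hi <- rep(0, length(ts))
    }
    data.frame(strategy = nm, nwt = nwt_grid, t = ts,
               net_benefit = est[1, ], treated_fraction = est[2, ],
               ci_lo = ci_lo, ci_hi = ci_hi)
  })
  structure(do.call(rbind, out),
            class = c("net_benefit_curves", "data.frame"))
}

#' @export
plot.net_benefit_curves <- function(x, ...) {
  strategies <- unique(x$strategy)
  cols <- stats::setNames(seq_along(strategies), strategies)
  graphics::plot(range(x$nwt), range(c(x$net_benefit, 0), na.rm = TRUE),
                 type = "n", xlab = "Number willing to treat",
                 ylab = "Net benefit", ...)
  graphics::abline(h = 0, col = "grey60", lty = 2)
  for (s in strategies) {
    xi <- x[x$strategy == s, ]
    xi <- xi[order(xi$nwt), ]
    graphics::lines(xi$nwt, xi$net_benefit, col = cols[s], lwd = 2)
  }
  graphics::legend("topleft", legend = strategies, col = cols, lwd = 2,
                   bty = "n")
  invisible(x)
}
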