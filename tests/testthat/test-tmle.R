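test_that("without covariate adjustment TMLE collapses to the difference in proportions", {
  co <- generate_cohort(600, dgp = constant_effect_dgp(rd = 0.04), seed = 17)
  q0 <- mean(co$y90[co$arm == "control"])
  q1 <- mean(co$y90[co$arm != "control"])
  qi <- cbind(q0 = rep(q0, nrow(co)), q1 = rep(q1, nrow(co)))
  est <- tmle_ate(co, c("any_steroid", "control"), q_init = qi, g = 0.5)
  expect_lt(abs(est$arr - (q0 - q1)), 1e-8)
  expect_lt(abs(est$rr - q1 / q0), 1e-8)
})

test_that("targeting solves the efficient-score equation", {
  co <- generate_cohort(900, seed = 19)
  est <- suppressMessages(tmle_ate(co, c("any_steroid", "control")))
  expect_lt(abs(mean(est$ic)), 1e-8)
  expect_true(est$mean1 > 0 && est$mean1 < 1)
  expect_true(est$ci_arr[1] < est$ci_arr[2])
  expect_true(est$ci_rr[1] < est$ci_rr[2])
})

test_that("estimates are invariant to patient ordering", {
  co <- generate_cohort(700, seed = 23)
  set.seed(1)
  perm <- sample(nrow(co))
  cop <- co[perm, ]
  attr(cop, "dgp") <- attr(co, "dgp")
  e1 <- suppressMessages(tmle_ate(co, c("hydrocortisone", "combination")))
  e2 <- suppressMessages(tmle_ate(cop, c("hydrocortisone", "combination")))
  expect_equal(e1$arr, e2$arr, tolerance = 1e-10)
  expect_equal(e1$rr, e2$rr, tolerance = 1e-10)
})

test_that("a constant-RR process is recovered at the pooled scale", {
  dgp <- constant_effect_dgp(rr = 0.89)
  co <- generate_cohort(2548, dgp = dgp, seed = 29)
  est <- suppressMessages(tmle_ate(co, c("any_steroid", "control")))
  expect_true(est$ci_rr[1] <= 0.89 && 0.89 <= est$ci_rr[2])
})

test_that("double robustness: known g corrects a misspecified outcome fit", {
  dgp <- constant_effect_dgp(rd = 0.05) # treated risk raised by 0.05
  co <- generate_cohort(20000, dgp = dgp, seed = 31)
  # grossly misspecified initial fit: constants far from the truth
  qi <- cbind(q0 = rep(0.2, nrow(co)), q1 = rep(0.2, nrow(co)))
  est <- suppressMessages(
    tmle_ate(co, c("any_steroid", "control"), q_init = qi))
  expect_lt(abs(est$arr - (-0.05)), 3 * est$se_arr)
})

test_that("per-trial estimates skip strata without both arms; pooled equals the single stratum when only one qualifies", {
  co <- generate_cohort(1500, seed = 37)
  res <- suppressMessages(suppressWarnings(
    pooled_and_per_trial(co, c("hydrocortisone", "control"))))
  # only the CORTICUS-like trial randomized hydrocortisone against placebo
  expect_equal(names(res$per_trial), "corticus")
  expect_equal(res$per_trial$corticus$arr, res$pooled$arr, tolerance = 1e-10)

  single <- co[co$trial == "crics", ]
  attr(single, "dgp") <- attr(co, "dgp")
  res2 <- suppressMessages(suppressWarnings(
    pooled_and_per_trial(single, c("combination", "control"))))
  expect_equal(res2$pooled$arr, res2$per_trial$crics$arr, tolerance = 1e-10)
})

test_that("invalid contrasts and degenerate propensities error", {
  co <- generate_cohort(300, seed = 41)
  expect_error(tmle_ate(co, c("any_steroid", "hydrocortisone")), "overlap")
  expect_error(tmle_ate(co, c("hydrocortisone", "control"), g = rep(1, 300)),
               "positivity")
})

test_that("short parameter-recovery run is unbiased at a known risk difference", {
  dgp <- constant_effect_dgp(rd = 0.05)
  ests <- vapply(1:60, function(r) {
    co <- generate_cohort(800, dgp = dgp, seed = 1000 + r)
    suppressMessages(tmle_ate(co, c("any_steroid", "control")))$arr
  }, 0)
  mc_se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - (-0.05)), 3 * mc_se)
})
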