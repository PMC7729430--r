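test_that("AUC handles separation, ties and the worked pair example", {
  expect_equal(auc_mann_whitney(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auc_mann_whitney(rep(0.4, 10), rep(0:1, 5)), 0.5)
  # cases {0.8, 0.6} vs controls {0.7, 0.2}: 3 of 4 pairs concordant
  scores <- c(0.8, 0.6, 0.7, 0.2)
  y <- c(1, 1, 0, 0)
  expect_equal(auc_mann_whitney(scores, y),
               auc_by_enumeration(scores, y))
  expect_equal(auc_mann_whitney(scores, y), 0.75)
  # a tied case-control pair counts one half: 3.5 of 4 pairs
  expect_equal(auc_mann_whitney(c(0.8, 0.6, 0.6, 0.2), y), 0.875)
  expect_error(auc_mann_whitney(scores, rep(1, 4)), "both outcome classes")
})

test_that("DeLong AUC equals exhaustive pairwise enumeration", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(20:200, 1)
    y <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(y)) < 2) next
    scores <- round(runif(n), sample(c(1, 2, 6), 1)) # induce ties sometimes
    d <- delong_auc_ci(scores, y)
    expect_equal(d$auc, auc_by_enumeration(scores, y), tolerance = 1e-12)
    expect_equal(d$auc, auc_mann_whitney(scores, y), tolerance = 1e-12)
    expect_true(d$ci[1] <= d$auc && d$auc <= d$ci[2])
    expect_true(all(d$ci >= 0 & d$ci <= 1))
  }
})

test_that("DeLong variance agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(8)
  y <- rbinom(300, 1, 0.4)
  scores <- plogis(y + rnorm(300))
  ours <- delong_auc_ci(scores, y)
  ref <- suppressMessages(pROC::ci.auc(pROC::roc(y, scores, quiet = TRUE),
                                       method = "delong"))
  expect_equal(ours$ci, as.numeric(ref[c(1, 3)]), tolerance = 1e-6)
})

test_that("DeLong interval width shrinks roughly as 1/sqrt(n)", {
  width <- vapply(c(200, 3200), function(n) {
    set.seed(n)
    y <- rep(0:1, n / 2)
    scores <- plogis(y + rnorm(n))
    d <- delong_auc_ci(scores, y)
    diff(d$ci)
  }, 0)
  expect_equal(width[1] / width[2], 4, tolerance = 0.8)
})

test_that("Brier score is the mean squared probability error", {
  expect_equal(brier_score(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_equal(brier_score(rep(0.5, 8), rbinom(8, 1, 0.5)), 0.25)
  expect_equal(brier_score(c(0.8, 0.3), c(1, 0)), 0.065)
  # decomposition sanity for calibrated scores
  set.seed(41)
  p <- runif(5000, 0.05, 0.95)
  yy <- rbinom(5000, 1, p)
  expect_equal(brier_score(p, yy), mean(p * (1 - p)), tolerance = 0.01)
})

test_that("calibration bins are equal-frequency and detect miscalibration", {
  set.seed(43)
  p <- runif(1000, 0.05, 0.95)
  y <- rbinom(1000, 1, p)
  cal <- calibration_curve(p, y, bins = 10)
  expect_equal(sum(cal$n), 1000)
  expect_true(all(cal$n == 100))
  # scores generated from their own truth: bins sit on the diagonal
  # (each bin's 95% interval may miss ~5% of the time, so allow one)
  covered <- cal$ci_lo <= cal$mean_pred & cal$mean_pred <= cal$ci_hi
  expect_gte(sum(covered), 9)

  # anti-calibrated scores: observed prevalence reverses across bins
  cal_rev <- calibration_curve(1 - p, y, bins = 5)
  expect_true(all(diff(cal_rev$observed) < 0))

  expect_warning(calibration_curve(rep(0.4, 50), rbinom(50, 1, 0.4)),
                 "single calibration bin")
})

test_that("cross-validated AUC pools out-of-fold predictions honestly", {
  co <- small_cohort(400, seed = 67)
  glm_fitter <- function(df, y) {
    fit <- glm(y ~ saps2 + sofa + age + lactate, binomial(),
               data = cbind(df, y = y))
    function(nd) predict(fit, nd, type = "response")
  }
  res <- cross_validated_auc(co, co$y90, glm_fitter, cv_plan(10, seed = 3))
  expect_gt(res$cv_auc, 0.6) # severity carries real signal
  expect_true(all(!is.na(res$oof)))

  # permutation null
  set.seed(5)
  yp <- sample(co$y90)
  resp <- cross_validated_auc(co, yp, glm_fitter, cv_plan(10, seed = 3))
  expect_gt(resp$cv_auc, 0.45)
  expect_lt(resp$cv_auc, 0.55)

  # leave-one-out agrees with 10-fold
  cos <- small_cohort(250, seed = 68)
  r10 <- cross_validated_auc(cos, cos$y90, glm_fitter, cv_plan(10, seed = 1))
  rloo <- cross_validated_auc(cos, cos$y90, glm_fitter,
                              cv_plan(nrow(cos), seed = 1))
  expect_lt(abs(r10$cv_auc - rloo$cv_auc), 0.02)
})
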