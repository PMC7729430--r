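# a hand-built ensemble stub whose predictions are a known function of the
# treatment feature; lets the ITE definition be checked exactly
stub_fsl <- function(risks = c(control = 0.5, hydrocortisone = 0.4,
                               combination = 0.45)) {
  fm <- structure(list(covariates = list(), miss_cols = character(),
                       has_arm = TRUE, has_trial = FALSE,
                       arm_levels = names(risks)),
                  class = "feature_map")
  structure(list(
    feature_map = fm,
    weights = c(only = 1),
    base_fits = list(only = list(
      predict = function(nd) unname(risks[as.character(nd$arm)])))),
    class = "fitted_super_learner")
}

test_that("the severity-model ITE is baseline risk times one minus RR", {
  expect_equal(ite_saps2(0.3, 1), 0)
  expect_equal(ite_saps2(0.5, 0.89), 0.055, tolerance = 1e-12)
  expect_equal(ite_saps2(0, 2.5), 0)
  p0 <- seq(0.01, 0.99, by = 0.01)
  expect_true(all(diff(ite_saps2(p0, 0.89)) > 0)) # increasing when RR < 1
  expect_true(all(diff(ite_saps2(p0, 1.2)) < 0))  # decreasing when RR > 1
  expect_error(ite_saps2(0.5, -1))
  expect_error(ite_saps2(1.4, 0.9))
})

test_that("severity ITEs never change sign across a cohort", {
  co <- small_cohort(800, seed = 51)
  its <- ite_saps2_cohort(co)
  expect_true(all(its$hydrocortisone > 0))
  expect_true(all(its$combination > 0))
  expect_true(all(its$d == pmax(its$hydrocortisone, its$combination)))
  # baseline risk comes from the SAPS II equation, so the ITE is monotone
  # in the score
  ord <- order(ifelse(is.na(co$saps2), median(co$saps2, na.rm = TRUE),
                      co$saps2))
  expect_true(all(diff(its$hydrocortisone[ord]) >= 0))
})

test_that("optimal-model ITE matches the counterfactual risk differences", {
  records <- data.frame(id = 1:3, arm = factor("control",
                        levels = c("control", "hydrocortisone",
                                   "combination")))
  fsl <- stub_fsl()
  est <- ite_optimal(fsl, records)
  expect_equal(unique(est$hydrocortisone), 0.10, tolerance = 1e-12)
  expect_equal(unique(est$combination), 0.05, tolerance = 1e-12)
  expect_equal(unique(est$d), 0.10, tolerance = 1e-12)
  expect_equal(unique(est$recommended), "hydrocortisone")

  # treatment-blind model: every ITE collapses to zero
  blind <- stub_fsl(c(control = 0.4, hydrocortisone = 0.4,
                      combination = 0.4))
  est0 <- ite_optimal(blind, records)
  expect_true(all(est0$d == 0))

  # ties are broken toward the lower-exposure regimen
  tie <- stub_fsl(c(control = 0.5, hydrocortisone = 0.42,
                    combination = 0.42))
  expect_equal(unique(ite_optimal(tie, records)$recommended),
               "hydrocortisone")

  no_arm <- stub_fsl()
  no_arm$feature_map$has_arm <- FALSE
  expect_error(ite_optimal(no_arm, records), "treatment as a feature")
})

test_that("fitted ITEs recover effect heterogeneity and agree with the TMLE on average", {
  co <- small_cohort(1500, seed = 53)
  fsl <- fit_super_learner(co, "y90", library = tiny_library(),
                           plan = cv_plan(5, seed = 6))
  est <- ite_optimal(fsl, co)
  truth <- true_ite(co)

  # positive rank correlation with the true per-patient effect
  expect_gt(cor(est$d, truth$d, method = "spearman"), 0.2)

  # qualitative interaction is expressible: both signs occur
  expect_gt(mean(est$hydrocortisone > 0), 0.05)
  expect_gt(mean(est$hydrocortisone < 0), 0.05)

  # cohort-mean ITE consistent with the targeted ATE for the same contrast
  tm <- suppressMessages(
    tmle_ate(co, c("hydrocortisone", "control"), fsl = fsl))
  expect_gt(mean(est$hydrocortisone), tm$ci_arr[1] - 0.02)
  expect_lt(mean(est$hydrocortisone), tm$ci_arr[2] + 0.02)
})
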