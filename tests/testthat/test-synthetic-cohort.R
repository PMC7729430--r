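test_that("same spec and seed give byte-identical cohorts", {
  a <- generate_cohort(500, seed = 42)
  b <- generate_cohort(500, seed = 42)
  expect_identical(a, b)
  c <- generate_cohort(500, seed = 43)
  expect_false(identical(a$y90, c$y90))
})

test_that("28-day deaths are nested within 90-day deaths", {
  co <- generate_cohort(3000, seed = 5)
  expect_true(all(co$y28 <= co$y90))
  expect_true(all(co[paste0("risk_", c("control", "hydrocortisone",
                                       "combination"))] >= 0))
})

test_that("marginal solver reproduces printed quartiles", {
  p <- fit_marginal(42, 55, 69, "truncnorm", lower = 0, upper = 163)
  # two-parameter family vs three quantile targets: least-squares
  # compromise within half a SAPS II point of each printed quartile
  q <- steroidite:::qtnorm(c(.25, .5, .75), p$mu, p$sigma, p$lower, p$upper)
  expect_equal(q, c(42, 55, 69), tolerance = 0.01)
  pl <- fit_marginal(1.8, 3.0, 5.5, "lognormal")
  ql <- exp(pl$mulog + pl$sdlog * qnorm(c(.25, .5, .75)))
  expect_equal(ql[2], 3.0, tolerance = 0.05)
})

test_that("null-effect process yields near-zero empirical arm differences", {
  dgp <- constant_effect_dgp(logor = 0)
  co <- generate_cohort(20000, dgp = dgp, seed = 7)
  p <- tapply(co$y90, co$arm, mean)
  nn <- table(co$arm)
  for (a in c("hydrocortisone", "combination")) {
    se <- sqrt(p["control"] * (1 - p["control"]) / nn["control"] +
                 p[a] * (1 - p[a]) / nn[a])
    expect_lt(abs(p["control"] - p[a]), 4 * se)
  }
  expect_equal(unname(dgp_true_ate(dgp, n_mc = 20000)),
               c(0, 0), tolerance = 1e-12)
})

test_that("true_ite is the per-arm risk difference and matches the dgp ATE", {
  co <- generate_cohort(300, seed = 3)
  ti <- true_ite(co)
  expect_equal(ti$hydrocortisone, co$risk_control - co$risk_hydrocortisone)
  expect_equal(ti$d, pmax(ti$hydrocortisone, ti$combination))

  # oracle consistency: cohort mean of the true ITE approaches the
  # numerically integrated population ATE
  big <- generate_cohort(40000, seed = 12)
  tib <- true_ite(big)
  truth <- dgp_true_ate(default_dgp(), n_mc = 200000)
  mc_se <- apply(tib[, c("hydrocortisone", "combination")], 2, sd) /
    sqrt(nrow(big))
  expect_lt(abs(mean(tib$hydrocortisone) - truth["hydrocortisone"]),
            3 * mc_se[1])
  expect_lt(abs(mean(tib$combination) - truth["combination"]),
            3 * mc_se[2])

  co$risk_control <- NULL
  expect_error(true_ite(co), "counterfactual")
})

test_that("missingness mechanisms blank values as configured", {
  dgp <- default_dgp()
  co <- generate_cohort(4000, dgp = dgp, seed = 21)

  dgp0 <- dgp
  dgp0$missingness <- list()
  expect_identical(apply_missingness(co, dgp0), co)

  # value-independent 30% mechanism: indicator mean within binomial error
  dgp3 <- dgp
  dgp3$missingness <- list(cortisol_increment = list(
    intercept = qlogis(0.3), slope = 0, center = 0))
  m <- apply_missingness(co, dgp3, seed = 8)
  rate <- mean(m$miss_cortisol_increment)
  expect_lt(abs(rate - 0.3), 4 * sqrt(0.3 * 0.7 / nrow(co)))
  expect_identical(m$y90, co$y90)
  expect_identical(m$arm, co$arm)
  expect_true(all(is.na(m$cortisol_increment) ==
                    (m$miss_cortisol_increment == 1)))

  # value-dependent mechanism: high increments more often observed, so the
  # observed-subsample mean exceeds the full-sample mean
  mn <- apply_missingness(co, dgp, seed = 9)
  expect_gt(mean(mn$cortisol_increment, na.rm = TRUE),
            mean(co$cortisol_increment))

  dgp_bad <- dgp
  dgp_bad$missingness <- list(nonexistent = list(intercept = 0))
  expect_error(apply_missingness(co, dgp_bad), "unknown covariate")
})

test_that("invalid configurations fail with informative errors", {
  expect_error(covariate_spec("x", "continuous", "truncnorm",
                              list(mu = NA, sigma = 1)), "x")
  expect_error(covariate_spec("grp", "categorical",
                              levels = c("a", "b"), probs = c(0.6, 0.6)),
               "sum to 1")
  tr <- steroidite:::default_trials()
  tr$control[1] <- 0.8 # probabilities no longer sum to 1
  expect_error(dgp_params(default_dgp()$baseline, default_dgp()$effects,
                          tr, c(annane = 0, corticus = 0, coiitss = 0,
                                crics = 0)),
               "sum to 1")
})

test_that("cohort CSV round-trips through the sidecar dictionary", {
  co <- apply_missingness(generate_cohort(120, seed = 2))
  path <- file.path(tempdir(), "cohort.csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_equal(levels(back$arm), levels(co$arm))
  expect_equal(back$y90, co$y90)
  expect_equal(back$saps2, co$saps2, tolerance = 1e-8)
  expect_equal(is.na(back$cortisol_increment), is.na(co$cortisol_increment))
  unlink(c(path, paste0(path, ".json")))
})
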