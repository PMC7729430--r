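test_that("threshold and number willing to treat are exact inverses", {
  th <- nwt_to_threshold(10)
  expect_identical(th$t * th$nwt, 1)
  expect_equal(th$t, 0.10)
  expect_equal(nwt_to_threshold(25)$t, 0.04)
  expect_equal(nwt_to_threshold(1)$t, 1)
  expect_equal(threshold_to_nwt(0.02)$nwt, 50)
  expect_error(nwt_to_threshold(0), "positive")
  expect_error(nwt_to_threshold(-3), "positive")
})

test_that("treat-all net benefit is ATE minus threshold", {
  expect_equal(net_benefit_treat_all(0.0511, 0.04), 0.0111,
               tolerance = 1e-12)
  expect_equal(net_benefit_treat_all(0.07, 0.07), 0)
  expect_equal(net_benefit_treat_all(0.0511, 0), 0.0511)
  expect_equal(net_benefit_treat_all(0.0511, nwt_to_threshold(25)), 0.0111,
               tolerance = 1e-12)
})

test_that("rule-based net benefit follows the event-rate-decrease definition", {
  r <- net_benefit_rule(c(0.10, 0.00), 0.05)
  expect_equal(r$event_rate_decrease, 0.05)
  expect_equal(r$treated_fraction, 0.5)
  expect_equal(r$net_benefit, 0.025)

  # nobody above threshold: collapses to treat-none
  r0 <- net_benefit_rule(c(0.01, 0.02), 0.05)
  expect_equal(r0$net_benefit, 0)
  expect_equal(r0$treated_fraction, 0)

  # everybody above threshold: collapses to treat-all at the mean effect
  d <- c(0.08, 0.12, 0.30)
  r1 <- net_benefit_rule(d, 0.05)
  expect_equal(r1$net_benefit, net_benefit_treat_all(mean(d), 0.05))
  expect_error(net_benefit_rule(numeric(), 0.05), "nonempty")
})

test_that("net benefit respects its decision-theoretic bounds", {
  set.seed(4)
  for (i in 1:20) {
    d <- rnorm(200, 0.03, 0.08)
    t <- runif(1, 0.01, 0.5)
    r <- net_benefit_rule(d, t)
    expect_gte(r$net_benefit, -t)
    expect_lte(r$net_benefit, mean(pmax(d, 0)))
    # curves meet the treat-none reference at the upper grid end
    expect_equal(net_benefit_rule(d, max(d) + 1e-9)$net_benefit, 0)
  }
  # when every estimated effect is positive, the rule meets treat-all as
  # the threshold vanishes
  d_pos <- abs(rnorm(200, 0.05, 0.03)) + 1e-4
  expect_equal(net_benefit_rule(d_pos, 1e-9)$net_benefit,
               net_benefit_treat_all(mean(d_pos), 1e-9), tolerance = 1e-8)
})

test_that("oracle net benefit uses true counterfactual risks", {
  co <- small_cohort(400, seed = 61)
  none <- oracle_net_benefit(co, rep(FALSE, nrow(co)), 0.04)
  expect_identical(none$net_benefit, 0)
  expect_identical(none$treated_fraction, 0)

  truth <- true_ite(co)
  t <- 0.04
  orc <- oracle_net_benefit(co, truth$d > t, t, regimen = truth$best)
  est_rule <- truth$d + rnorm(nrow(co), 0, 0.05) # a noisy estimated rule
  noisy <- oracle_net_benefit(co, est_rule > t, t, regimen = truth$best)
  expect_gte(orc$net_benefit, noisy$net_benefit)

  plain <- co
  plain$risk_control <- NULL
  expect_error(oracle_net_benefit(plain, truth$d > t, t), "synthetic")
})

test_that("the true-effect threshold rule is optimal over all assignments", {
  # exhaustive enumeration of every treatment assignment on 10 patients
  set.seed(9)
  n <- 10
  co <- data.frame(risk_control = runif(n, 0.2, 0.8))
  co$risk_hydrocortisone <- pmin(pmax(
    co$risk_control - runif(n, -0.15, 0.25), 0.01), 0.99)
  t <- 0.1
  d <- co$risk_control - co$risk_hydrocortisone
  best <- -Inf
  for (mask in 0:(2^n - 1)) {
    treat <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    nb <- oracle_net_benefit(co, treat, t)$net_benefit
    if (nb > best) best <- nb
  }
  rule_nb <- oracle_net_benefit(co, d > t, t)$net_benefit
  expect_equal(rule_nb, best, tolerance = 1e-12)
})

test_that("curves are consistent, reproducible and order-invariant", {
  set.seed(12)
  n <- 300
  d <- rnorm(n, 0.05, 0.06)
  strata <- rep(c("a", "b", "c"), each = 100)
  strategies <- list(
    treat_none = list(type = "treat_none"),
    treat_all = list(type = "treat_all", d = d),
    rule = list(type = "rule", d = d))
  cur <- net_benefit_curves(strategies, nwt_grid = c(5, 10, 25, 50),
                            bootstrap_B = 80, seed = 3, strata = strata)
  expect_true(all(cur$net_benefit[cur$strategy == "treat_none"] == 0))
  ta <- cur[cur$strategy == "treat_all", ]
  expect_equal(ta$net_benefit,
               vapply(ta$t, function(t) net_benefit_treat_all(mean(d), t), 0),
               tolerance = 1e-12)
  ru <- cur[cur$strategy == "rule", ]
  expect_true(all(diff(ru$treated_fraction[order(ru$t)]) <= 0))

  # same seed, permuted patients: identical curves and bands
  p <- sample(n)
  strategies2 <- list(
    treat_none = list(type = "treat_none"),
    treat_all = list(type = "treat_all", d = d[p]),
    rule = list(type = "rule", d = d[p]))
  cur2 <- net_benefit_curves(strategies2, nwt_grid = c(5, 10, 25, 50),
                             bootstrap_B = 80, seed = 3, strata = strata[p])
  expect_equal(cur, cur2, tolerance = 1e-12)

  expect_warning(
    net_benefit_curves(strategies, nwt_grid = 25, bootstrap_B = 1),
    "omitted")
})
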