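test_that("weight optimizer handles degenerate and separable inputs", {
  y <- rep(0:1, each = 50)
  one <- matrix(plogis(rnorm(100)), ncol = 1)
  expect_equal(optimize_weights(one, y), 1)
  expect_error(optimize_weights(one, rep(1, 100)), "constant")

  # separable first column vs noise: brute-force grid over the 1-simplex
  # confirms the optimum, and the optimizer puts ~all weight on column 1
  set.seed(2)
  l1 <- cbind(good = y * 0.8 + 0.1, noise = runif(100))
  w <- optimize_weights(l1, y)
  expect_gte(w[1], 0.99)
  grid <- seq(0, 1, by = 0.01)
  grid_auc <- vapply(grid, function(a)
    auc_mann_whitney(drop(l1 %*% c(a, 1 - a)), y), 0)
  expect_equal(auc_mann_whitney(drop(l1 %*% w), y), max(grid_auc),
               tolerance = 1e-9)

  # appending a constant column cannot change the achievable optimum
  l2 <- cbind(l1, const = 0.5)
  w2 <- optimize_weights(l2, y)
  expect_equal(auc_mann_whitney(drop(l2 %*% w2), y), max(grid_auc),
               tolerance = 1e-9)
})

test_that("a single-learner library collapses to that learner", {
  co <- small_cohort(400, seed = 31)
  fsl <- fit_super_learner(co, "y90", library = tiny_library()[1],
                           plan = cv_plan(5, seed = 3))
  expect_equal(unname(fsl$weights), 1)
  single <- fit_learner(learner_spec("logistic"),
                        build_design(fsl$feature_map, co), co$y90)
  expect_equal(unname(predict_risk(fsl, co)),
               unname(single$predict(build_design(fsl$feature_map, co))),
               tolerance = 1e-10)
})

test_that("duplicating a learner leaves ensemble predictions unchanged", {
  co <- small_cohort(400, seed = 32)
  lib1 <- tiny_library()[1]
  lib2 <- list(logistic = learner_spec("logistic"),
               logistic_copy = learner_spec("logistic_copy", "logistic"))
  f1 <- fit_super_learner(co, "y90", library = lib1, plan = cv_plan(5, seed = 3))
  f2 <- fit_super_learner(co, "y90", library = lib2, plan = cv_plan(5, seed = 3))
  expect_equal(predict_risk(f1, co), predict_risk(f2, co), tolerance = 1e-8)
})

test_that("level-1 predictions are honest and the fit is deterministic", {
  co <- small_cohort(500, seed = 33)
  plan <- cv_plan(5, seed = 9)
  f1 <- fit_super_learner(co, "y90", library = sim_library(), plan = plan)
  f2 <- fit_super_learner(co, "y90", library = sim_library(), plan = plan)
  expect_equal(f1$weights, f2$weights, tolerance = 1e-6)
  expect_equal(f1$cv_auc, f2$cv_auc, tolerance = 1e-10)

  # ensemble CV-AUC can never fall below the best single learner
  single <- apply(f1$level1, 2, auc_mann_whitney, y = co$y90)
  expect_gte(f1$cv_auc, max(single) - 1e-9)

  # discrete selection puts all weight on the best single learner
  fd <- fit_super_learner(co, "y90", library = sim_library(), plan = plan,
                          metalearner = "discrete")
  expect_equal(sort(unname(fd$weights)), c(0, 0, 0, 1))
  expect_equal(fd$cv_auc, max(single), tolerance = 1e-10)

  # honesty: permuted labels leave nothing to learn
  cop <- co
  set.seed(77)
  cop$y90 <- sample(co$y90)
  fp <- fit_super_learner(cop, "y90", library = tiny_library(),
                          plan = cv_plan(10, seed = 5))
  expect_gt(fp$cv_auc, 0.40)
  expect_lt(fp$cv_auc, 0.60)
})

test_that("counterfactual prediction overrides the treatment feature", {
  co <- small_cohort(400, seed = 34)
  fsl <- fit_super_learner(co, "y90", library = tiny_library(),
                           plan = cv_plan(5, seed = 4))
  own <- predict_risk(fsl, co)
  manual <- rep(NA_real_, nrow(co))
  for (a in levels(co$arm)) {
    idx <- co$arm == a
    manual[idx] <- predict_risk(fsl, co[idx, ], arm_override = a)
  }
  expect_equal(own, manual, tolerance = 1e-10)
  expect_true(all(predict_risk(fsl, co, arm_override = "combination") >= 0))
  expect_error(predict_risk(fsl, co, arm_override = "placebo"),
               "unknown arm")
})

test_that("ensemble risk approaches the true risk as n grows", {
  dgp <- default_dgp()
  err <- vapply(c(400, 2500), function(n) {
    co <- generate_cohort(n, dgp = dgp, seed = 55)
    fsl <- fit_super_learner(co, "y90", library = tiny_library(),
                             plan = cv_plan(5, seed = 5))
    truth <- co[[paste0("risk_", "control")]]
    idx <- co$arm == "control"
    mean(abs(predict_risk(fsl, co[idx, ]) - truth[idx]))
  }, 0)
  expect_lt(err[2], err[1])
  expect_lt(err[2], 0.08)
})

test_that("degenerate inputs are rejected", {
  co <- small_cohort(200, seed = 36)
  co$y90 <- 0L
  expect_error(fit_super_learner(co, "y90", library = tiny_library()),
               "both outcome classes")
  co2 <- small_cohort(200, seed = 37)
  co2$pathogen <- factor("viral") # level unseen by a trained feature map
  fsl <- fit_super_learner(small_cohort(200, seed = 38), "y90",
                           library = tiny_library(),
                           plan = cv_plan(4, seed = 2))
  expect_error(predict_risk(fsl, co2), "pathogen")
})
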