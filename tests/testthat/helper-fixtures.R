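# shared fixtures: small cohorts and learner libraries used across tests

small_cohort <- function(n = 600, seed = 11, dgp = default_dgp()) {
  generate_cohort(n, dgp = dgp, seed = seed)
}

# two cheap learners: enough to exercise the stacking machinery quickly
tiny_library <- function() {
  list(logistic = learner_spec("logistic"),
       logistic_interactions = learner_spec("logistic_interactions"))
}

sim_library <- function() {
  list(logistic = learner_spec("logistic"),
       gam = learner_spec("gam"),
       random_forest = learner_spec("random_forest",
                                    hyper = list(num.trees = 200)),
       gradient_boosting = learner_spec("gradient_boosting",
                                        hyper = list(nrounds = 80)))
}

# exhaustive pairwise AUC: the independent oracle for rank-based AUC code
auc_by_enumeration <- function(scores, y) {
  cases <- scores[y == 1]; controls <- scores[y == 0]
  cmp <- outer(cases, controls, function(a, b)
    (a > b) + 0.5 * (a == b))
  mean(cmp)
}
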