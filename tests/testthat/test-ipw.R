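test_that("strategy probabilities follow the branch structure", {
  cohort <- simulate_two_period(200, seed = 21)
  const_model <- fit_treatment_models(
    cohort, learner = function(y, X, newX) rep(0.3, nrow(newX)),
    prob_floor = 0
  )
  # delivered at t - 1: probability one
  p2 <- strategy_probability(const_model, cohort, k = 2, t = 2)
  delivered <- cohort$T_D < 2
  expect_true(all(p2[delivered] == 1))
  # before the start time: complement of initiation probability
  und_atrisk <- cohort$T_D >= 1 & gestinit:::at_risk_of_initiation(cohort, 1)
  p1 <- strategy_probability(const_model, cohort, k = 2, t = 1)
  expect_true(all(p1[und_atrisk] == 0.7))
  # at the start time: initiation probability itself
  at2 <- cohort$T_D >= 2 & gestinit:::at_risk_of_initiation(cohort, 2)
  expect_true(all(p2[at2] == 0.3))
  # past the start time: automatically one
  expect_true(all(strategy_probability(const_model, cohort, k = 1, t = 2) == 1))
})

test_that("cumulative weights multiply only the random factors", {
  # constant initiation probability 0.3, K = 4, strategy k = 3:
  # a follower undelivered through time 3 has w^3(4) = 1/(0.7 * 0.7 * 0.3)
  panel <- make_panel(
    A = list(c(0, 0, 1, 1), c(0, 1, 1, 1), c(0, NA, NA, NA)),
    D = list(c(0, 0, 0, 1), c(0, 0, 0, 1), c(1, 1, 1, 1)),
    W = list(rep(1, 4), rep(0, 4), c(1, NA, NA, NA)),
    Y = c(1, 0, 1)
  )
  cohort <- validate_cohort(panel)
  models <- fit_treatment_models(
    cohort, learner = function(y, X, newX) rep(0.3, nrow(newX)),
    prob_floor = 0
  )
  wt <- weight_trajectory(models, cohort, k = 3)
  expect_equal(wt$weights[1, 4], 1 / (0.7 * 0.7 * 0.3), tolerance = 1e-12)
  # subject 2 broke strategy 3 by initiating at time 2: weight zero from then
  expect_equal(wt$weights[2, 2:4], rep(0, 3))
  # never-initiator delivering at t = 1, strategy 3: only the first factor
  # is random, later factors are one by the delivery branch
  expect_equal(wt$weights[3, ], rep(1 / 0.7, 4), tolerance = 1e-12)
  # weights vanish exactly where adherence is broken
  expect_true(all((wt$weights == 0) == (wt$S == 0)))
})

test_that("zero strategy probability for a follower raises a positivity error", {
  P <- matrix(c(0.5, 0), 1, 2)
  S <- matrix(c(1, 1), 1, 2)
  expect_error(cumulative_weights(P, S), "positivity")
  # harmless when the subject is not a follower
  expect_silent(cumulative_weights(P, matrix(c(1, 0), 1, 2)))
})

test_that("equal weights reduce the IPW estimate to the follower mean", {
  # everyone undelivered until K, nobody initiates, constant oracle
  # probabilities: all subjects follow the never-initiate strategy with the
  # same weight, so the estimate is the plain sample mean
  set.seed(22)
  n <- 40
  panel <- make_panel(
    A = replicate(n, c(0, 0), simplify = FALSE),
    D = replicate(n, c(0, 1), simplify = FALSE),
    W = replicate(n, rbinom(2, 1, 0.5), simplify = FALSE),
    Y = rbinom(n, 1, 0.5)
  )
  cohort <- validate_cohort(panel)
  models <- fit_treatment_models(
    cohort, learner = function(y, X, newX) rep(0.5, nrow(newX)),
    prob_floor = 0
  )
  est <- ipw_estimate(cohort, k = 3, models = models)
  expect_equal(est$estimate, mean(cohort$Y), tolerance = 1e-12)
  expect_identical(est$diagnostics$n_followers, as.integer(n))
  expect_equal(est$diagnostics$max_weight, 4)
})

test_that("no followers through K is an estimation error", {
  panel <- make_panel(
    A = list(c(1, 1), c(1, NA)), D = list(c(0, 1), c(1, 1)),
    W = list(c(1, 0), c(0, NA)), Y = c(1, 0)
  )
  cohort <- validate_cohort(panel)
  expect_error(ipw_estimate(cohort, k = 3,
                            models = fit_treatment_models(cohort,
                                                          "intercept")),
               "not estimable|no subject follows|positivity|at-risk")
})

test_that("saturated IPW matches the brute-force g-formula enumeration", {
  cohort <- simulate_two_period(500, seed = 23)
  models <- fit_treatment_models(cohort, learner = "saturated",
                                 prob_floor = 0)
  for (k in 1:3) {
    oracle <- gformula_oracle_2p(cohort, k)
    est <- ipw_estimate(cohort, k, models = models)
    expect_equal(est$estimate, oracle, tolerance = 1e-8)
  }
  # normalization: mean of w^k(K) * S^k(K) is one under saturated MLE cells
  for (k in 1:3) {
    wt <- weight_trajectory(models, cohort, k)
    expect_equal(mean(wt$weights[, 2]), 1, tolerance = 1e-10)
  }
})

test_that("weight truncation at the 100th percentile changes nothing", {
  cohort <- simulate_two_period(300, seed = 24)
  models <- fit_treatment_models(cohort, learner = "logistic")
  e1 <- ipw_estimate(cohort, 2, models = models)
  e2 <- ipw_estimate(cohort, 2, models = models, truncate_at = 1)
  expect_equal(e1$estimate, e2$estimate, tolerance = 1e-12)
})

test_that("the stacked MSM coincides with per-strategy weighted means", {
  cohort <- simulate_two_period(400, seed = 25)
  models <- fit_treatment_models(cohort, learner = "logistic")
  msm <- ipw_msm(cohort, ks = 2:3, models = models)
  per_k <- vapply(2:3, function(k) ipw_estimate(cohort, k,
                                                models = models)$estimate,
                  numeric(1))
  expect_equal(msm$means$estimate, per_k, tolerance = 1e-10)
  expect_equal(msm$contrasts$estimate, per_k[1] - per_k[2],
               tolerance = 1e-10)
})

test_that("RCT-like initiation recovers the strategy-arm mean within simulation error", {
  # known constant initiation probability supplied as an oracle model
  spec <- scenario_spec(1, n = 20000,
                        coefs = list(a_w = 0, a_int = qlogis(0.3)))
  cohort <- simulate_cohort(spec, seed = 26)
  models <- fit_treatment_models(
    cohort, learner = function(y, X, newX) rep(0.3, nrow(newX)),
    prob_floor = 0
  )
  truth <- counterfactual_truth(spec, ks = 3, n = 2e5, seed = 27)
  est <- ipw_estimate(cohort, 3, models = models)
  # follower subsample is a fraction of n; allow a generous sampling margin
  expect_lt(abs(est$estimate - truth$means$value[1]), 0.03)
})
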