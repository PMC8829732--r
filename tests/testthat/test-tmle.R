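test_that("continuous outcomes scale to the unit interval and back", {
  b <- bound_continuous_outcome(c(2500, 4000), delta = 0)
  expect_equal(b$scaled, c(0, 1))
  y <- c(2500, 3100, 3600, 4000)
  b2 <- bound_continuous_outcome(y, delta = 0.005)
  expect_equal(range(b2$scaled), c(0.005, 0.995))
  expect_equal(b2$to_original(b2$scaled), y, tolerance = 1e-12)
  expect_error(bound_continuous_outcome(rep(3, 5)), "constant")
})

test_that("the targeting step solves the weighted score", {
  set.seed(41)
  n <- 200
  y <- rbinom(n, 1, 0.4)
  # constant offset + equal weights: update lands on the weighted mean
  upd <- tmle_targeting_step(rep(0.5, n), y, rep(1, n))
  expect_equal(unique(round(upd$predictions, 12)), round(mean(y), 12))
  expect_lt(abs(upd$score), 1e-8)
  # predictions already solving the score are left unchanged
  p <- rep(mean(y), n)
  upd2 <- tmle_targeting_step(p, y, rep(1, n))
  expect_equal(upd2$epsilon, 0)
  expect_equal(upd2$predictions, p)
  # entries outside the update subset are untouched
  upd3 <- tmle_targeting_step(rep(0.5, n), y, rep(1, n),
                              update_subset = 1:50)
  expect_equal(upd3$predictions[51:n], rep(0.5, n - 50))
  # all-zero weights: no followers to fluctuate on
  expect_error(tmle_targeting_step(rep(0.5, n), y, rep(0, n)),
               "weights are zero")
})

test_that("two-period TMLE follows the worked step sequence", {
  cohort <- simulate_two_period(400, seed = 42)
  est <- tmle_estimate(cohort, k = 2, treatment_learner = "logistic",
                       outcome_learner = "logistic")
  steps <- est$diagnostics$steps
  # first backward step fits among D(1) = 0 and updates those subjects;
  # second step fits among everyone (D(0) = 0)
  expect_identical(steps[[2]]$n_update, sum(cohort$T_D >= 2))
  expect_identical(steps[[1]]$n_update, cohort$n)
  expect_identical(steps[[2]]$n_fit, sum(cohort$T_D >= 2))
  expect_identical(steps[[1]]$n_fit, cohort$n)
  # each fluctuation solves its weighted score equation
  expect_true(all(abs(est$diagnostics$scores) < 1e-6))
  expect_true(est$estimate >= 0 && est$estimate <= 1)
})

test_that("saturated TMLE equals the enumeration oracle with null fluctuations", {
  cohort <- simulate_two_period(500, seed = 23)
  models <- fit_treatment_models(cohort, learner = "saturated",
                                 prob_floor = 0)
  for (k in 1:3) {
    est <- tmle_estimate(cohort, k, models = models,
                         outcome_learner = "saturated")
    expect_equal(est$estimate, gformula_oracle_2p(cohort, k),
                 tolerance = 1e-8)
    expect_equal(est$diagnostics$epsilons, rep(0, 2))
  }
})

test_that("score equations are solved on four-period cohorts", {
  for (sc in c(1, 3)) {
    cohort <- simulate_cohort(scenario_spec(sc, n = 500), seed = 43 + sc)
    for (k in c(2, 5)) {
      est <- tmle_estimate(cohort, k)
      expect_true(all(abs(est$diagnostics$scores) < 1e-6))
    }
  }
})

test_that("continuous outcomes stay within the observed range and back-transform", {
  cohort <- simulate_cohort(scenario_spec(2, n = 600), seed = 44)
  # birthweight-like outcome increasing with gestational length
  set.seed(45)
  cohort$Y <- 2400 + 400 * cohort$T_D + rnorm(cohort$n, 0, 300)
  cohort$Y <- pmin(pmax(cohort$Y, 1500), 4800)
  est <- tmle_estimate(cohort, k = 3, scale_delta = 0.005)
  expect_true(est$estimate >= min(cohort$Y) && est$estimate <= max(cohort$Y))
  g <- gcomp_estimate(cohort, k = 3, learner = "linear")
  expect_lt(abs(est$estimate - g$estimate), 100)
})

test_that("double robustness holds in either direction of misspecification", {
  spec <- scenario_spec(2, n = 1000)
  truth <- counterfactual_truth(spec, ks = 2:3, n = 3e5, seed = 46)
  tc <- truth$contrasts$value[1]
  reps <- 40
  res <- vapply(seq_len(reps), function(r) {
    ch <- simulate_cohort(spec, seed = 4600 + r)
    tm_ok <- fit_treatment_models(ch, "logistic")
    tm_bad <- fit_treatment_models(ch, "intercept")
    c(
      mis_out = tmle_estimate(ch, 2, models = tm_ok,
                              outcome_learner = "intercept")$estimate -
        tmle_estimate(ch, 3, models = tm_ok,
                      outcome_learner = "intercept")$estimate,
      mis_trt = tmle_estimate(ch, 2, models = tm_bad)$estimate -
        tmle_estimate(ch, 3, models = tm_bad)$estimate
    )
  }, numeric(2))
  for (row in 1:2) {
    expect_lt(abs(mean(res[row, ]) - tc),
              3 * sd(res[row, ]) / sqrt(reps) + 0.005)
  }
})
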