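test_that("validation derives delivery times and enforces panel structure", {
  panel <- make_panel(
    A = list(c(0, NA, NA), c(0, 0, 1)),
    D = list(c(0, 1, 1), c(0, 0, 1)),
    W = list(c(1, 1, NA), c(0, 1, 0)),
    Y = c(1, 0)
  )
  # exposure unrecorded in the delivery interval is tolerated (recoded)
  expect_message(cohort <- validate_cohort(panel), "recoded")
  expect_s3_class(cohort, "preg_cohort")
  expect_identical(cohort$A[1, 2], 0)
  expect_identical(cohort$T_D, c(2L, 3L))
  expect_identical(cohort$K, 3L)
  # round trip through the long format
  expect_identical(validate_cohort(tibble::as_tibble(cohort))$T_D, cohort$T_D)
})

test_that("structural violations are rejected with informative errors", {
  base <- list(
    A = list(c(0, 0, NA)), D = list(c(0, 1, 1)),
    W = list(c(1, 0, NA)), Y = 1
  )
  # non-monotone delivery
  bad <- base; bad$D <- list(c(0, 1, 0))
  expect_error(validate_cohort(do.call(make_panel, bad)), "not monotone")
  # exposure recorded strictly after delivery
  bad <- base; bad$A <- list(c(0, 0, 1))
  expect_error(validate_cohort(do.call(make_panel, bad)),
               "exposure recorded after delivery")
  # covariate recorded strictly after delivery
  bad <- base; bad$W <- list(c(1, 0, 1))
  expect_error(validate_cohort(do.call(make_panel, bad)),
               "recorded after delivery")
  # missing outcome
  bad <- base; bad$Y <- NA
  expect_error(validate_cohort(do.call(make_panel, bad)), "outcome Y")
  # undelivered at K
  bad <- base; bad$D <- list(c(0, 0, 0)); bad$A <- list(c(0, 0, 0))
  bad$W <- list(c(1, 0, 1))
  expect_error(validate_cohort(do.call(make_panel, bad)), "delivered by time K")
  # inconsistent K across subjects
  p1 <- make_panel(A = list(c(0, 0, NA)), D = list(c(0, 1, 1)),
                   W = list(c(1, 0, NA)), Y = 1)
  p2 <- make_panel(A = list(c(0, 0)), D = list(c(0, 1)),
                   W = list(c(1, 0)), Y = 0)
  p2$subject_id <- 2
  expect_error(validate_cohort(dplyr::bind_rows(p1, p2)), "K differs")
})

test_that("censoring columns are accepted but ignored", {
  panel <- make_panel(A = list(c(0, NA)), D = list(c(1, 1)),
                      W = list(c(1, NA)), Y = 1)
  # subject delivered at t = 1: A(1), W(1) observed; rest NA
  panel$C <- 0
  expect_message(cohort <- validate_cohort(panel), "ignored")
  expect_false("C" %in% names(tibble::as_tibble(cohort)))
})

test_that("adherence indicators match the worked compatibility examples", {
  # subject 1: no exposure by time 2, undelivered until the end (K = 4);
  # subject 2: never initiated, delivered at time 2;
  # subject 3: initiated exactly at time 2, delivered at the end
  panel <- make_panel(
    A = list(c(0, 0, 0, 1), c(0, 0, NA, NA), c(0, 1, 1, 1)),
    D = list(c(0, 0, 0, 1), c(0, 1, 1, 1), c(0, 0, 0, 1)),
    W = list(c(1, 0, 1, 0), c(0, 1, NA, NA), c(1, 1, 0, 0)),
    Y = c(1, 0, 1)
  )
  cohort <- validate_cohort(panel)
  S <- function(k, t) strategy_indicator(cohort, k, t)
  # untreated through time 2: compatible with every later start
  expect_identical(S(2, 1)[1], 1L); expect_identical(S(3, 1)[1], 1L)
  expect_identical(S(3, 2)[1], 1L); expect_identical(S(4, 1)[1], 1L)
  expect_identical(S(4, 2)[1], 1L)
  expect_identical(S(1, 1)[1], 0L); expect_identical(S(1, 2)[1], 0L)
  expect_identical(S(2, 2)[1], 0L)
  # never-initiator delivered at time 2 follows all strategies with k > 2
  for (k in 3:5) for (t in 1:4) expect_identical(S(k, t)[2], 1L)
  expect_identical(S(2, 2)[2], 0L)
  # initiator at k1 = 2: adherent to k = 2 at all times, to k = 3 only
  # before time 2
  for (t in 1:4) expect_identical(S(2, t)[3], 1L)
  expect_identical(S(3, 1)[3], 1L)
  for (t in 2:4) expect_identical(S(3, t)[3], 0L)
})

test_that("adherence indicators satisfy monotonicity, coverage, and agree with the brute-force definition", {
  for (seed in 1:3) {
    cohort <- simulate_cohort(scenario_spec(sample(1:4, 1), n = 150),
                              seed = seed)
    for (k in 1:(cohort$K + 1)) {
      Smat <- vapply(seq_len(cohort$K),
                     function(t) strategy_indicator(cohort, k, t),
                     integer(cohort$n))
      # non-increasing in t: adherence once broken stays broken
      expect_true(all(t(apply(Smat, 1, diff)) <= 0))
      # brute-force re-derivation from the definition
      for (t in seq_len(cohort$K)) {
        expect_identical(Smat[, t], oracle_strategy_indicator(cohort, k, t))
      }
    }
    # every observed history is compatible with at least one strategy
    for (t in seq_len(cohort$K)) {
      any_k <- rowSums(vapply(1:(cohort$K + 1),
                              function(k) strategy_indicator(cohort, k, t),
                              integer(cohort$n)))
      expect_true(all(any_k >= 1))
    }
  }
})

test_that("strategy indicator table is tidy and consistent with the matrix form", {
  cohort <- simulate_cohort(scenario_spec(1, n = 50), seed = 4)
  tab <- strategy_indicators(cohort, ks = c(2, 5))
  expect_identical(names(tab), c("subject_id", "k", "time", "S"))
  expect_identical(nrow(tab), 2L * cohort$K * cohort$n)
  sub <- tab[tab$k == 5 & tab$time == cohort$K, ]
  expect_identical(sub$S, strategy_indicator(cohort, 5, cohort$K))
})
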