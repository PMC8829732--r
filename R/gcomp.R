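#' One backward step of the iterated-expectation recursion
#'
#' Given the nested conditional-expectation values at time `t + 1`, computes
#' the values at time `t`: subjects already delivered by `t - 1` keep their
#' known outcome `Y` (delivery pass-through), and undelivered subjects
#' receive regression predictions with the exposure history set to the
#' values implied by strategy `k`.
#'
#' @param current Numeric vector of pseudo-outcome values at `t + 1`, over
#'   all subjects (initialise the recursion with `Y`).
#' @param cohort A `preg_cohort`.
#' @param t Time of the step.
#' @param k Strategy start time, in `1..K+1`.
#' @inheritParams fit_outcome_step
#' @return A list with `values` (vector over all subjects at time `t`) and
#'   `step` (the fitted `outcome_step`).
#' @export
gcomp_backward_step <- function(current, cohort, t, k, learner = "logistic",
                                strict = FALSE) {
  step <- fit_outcome_step(current, cohort, t, k, learner, strict)
  values <- cohort$Y            # delivered-by-(t-1) subjects keep Y
  values[step$subset] <- step$predictions
  list(values = values, step = step)
}

#' G-computation estimate of E(Y^k)
#'
#' Iterated-conditional-expectation G-computation: initialise the
#' pseudo-outcome at the observed outcome, run backward regression steps
#' from `t = K` down to `1` with delivery pass-through at each step, and
#' average the final values over all subjects.
#'
#' @param cohort A `preg_cohort`.
#' @param k Strategy start time, in `1..K+1`.
#' @param learner Outcome-step learner; `NULL` (default) picks
#'   probability-scale logistic for outcomes bounded in `[0, 1]` and linear
#'   regression otherwise.
#' @inheritParams fit_outcome_step
#' @return A `gest_estimate` whose diagnostics record the per-step fitting
#'   sample sizes and the full matrix of iterate values.
#' @export
gcomp_estimate <- function(cohort, k, learner = NULL, strict = FALSE) {
  check_cohort(cohort)
  learner <- learner %||% default_outcome_learner(cohort$Y)
  K <- cohort$K
  values <- cohort$Y
  n_fit <- integer(K)
  iterates <- matrix(NA_real_, cohort$n, K)
  for (t in seq(K, 1)) {
    stepped <- gcomp_backward_step(values, cohort, t, k, learner, strict)
    values <- stepped$values
    n_fit[t] <- stepped$step$n_fit
    iterates[, t] <- values
  }
  new_gest_estimate(
    "gcomp", k, mean(values),
    diagnostics = list(n = cohort$n, n_fit = n_fit, iterates = iterates)
  )
}
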