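#' Scale a continuous outcome into the unit interval
#'
#' Affine map of a bounded continuous outcome onto `[delta, 1 - delta]`, so
#' the logistic targeting machinery (which needs outcomes in `[0, 1]`) can
#' be applied, together with the inverse transform. Because the map is
#' affine, a mean on the scaled scale back-transforms exactly.
#'
#' @param y Numeric outcome values with finite `min < max`.
#' @param delta Shrinkage away from the boundary, in `[0, 0.5)`. Default 0.
#' @return A list with `scaled` (the transformed values), `to_original`
#'   (inverse transform function), and the recorded `range`.
#' @export
bound_continuous_outcome <- function(y, delta = 0) {
  rng <- range(y)
  if (!all(is.finite(rng)) || rng[1] == rng[2]) {
    abort("outcome is constant (or non-finite); cannot scale to [0, 1]")
  }
  if (delta < 0 || delta >= 0.5) abort("delta must be in [0, 0.5)")
  scaled <- delta + (1 - 2 * delta) * (y - rng[1]) / (rng[2] - rng[1])
  to_original <- function(v) rng[1] + (v - delta) * (rng[2] - rng[1]) / (1 - 2 * delta)
  list(scaled = scaled, to_original = to_original, range = rng)
}

# intercept-only logistic fluctuation with offset: solves the weighted score
# sum(w * (y - expit(offset + eps))) = 0 for eps
solve_fluctuation <- function(offset, y, w, tol = 1e-12, bound = 30) {
  sw <- sum(w)
  if (sw <= 0) abort("all weights are zero in the targeting subset (no followers)")
  score <- function(eps) sum(w * (y - plogis(offset + eps))) / sw
  s0 <- score(0)
  if (abs(s0) < tol) return(list(epsilon = 0, score = s0))
  lo <- score(bound); hi <- score(-bound)
  if (s0 > 0 && lo >= 0) return(list(epsilon = bound, score = lo))
  if (s0 < 0 && hi <= 0) return(list(epsilon = -bound, score = hi))
  root <- uniroot(score, interval = c(-bound, bound), tol = tol)
  list(epsilon = root$root, score = score(root$root))
}

#' TMLE targeting (fluctuation) step
#'
#' Updates outcome-regression predictions by an intercept-only logistic
#' regression of the pseudo-outcome with the logit of the current
#' predictions as offset and the cumulative strategy weights as observation
#' weights, fitted on the update subset (undelivered subjects). Entries
#' outside the subset are returned unchanged — in the full algorithm those
#' are the known outcomes of already-delivered subjects, which the
#' targeting must not touch.
#'
#' @param predictions Numeric vector of current predictions in `(0, 1)`
#'   over all subjects.
#' @param pseudo_outcome Numeric vector in `[0, 1]` over all subjects.
#' @param weights Non-negative weights over all subjects (zero for subjects
#'   not following the strategy).
#' @param update_subset Integer indices of the subjects to update (default:
#'   everyone).
#' @param fluctuation `"logistic"` (default) or `"linear"` (weighted mean
#'   residual added on the identity scale).
#' @return A list with `predictions` (updated vector), `epsilon` (the
#'   fitted fluctuation intercept), and `score` (weighted mean residual
#'   after the update, which the logistic solver drives to zero).
#' @export
tmle_targeting_step <- function(predictions, pseudo_outcome, weights,
                                update_subset = NULL,
                                fluctuation = c("logistic", "linear")) {
  fluctuation <- match.arg(fluctuation)
  idx <- update_subset %||% seq_along(predictions)
  p <- predictions[idx]
  y <- pseudo_outcome[idx]
  w <- weights[idx]
  if (sum(w) <= 0) abort("all weights are zero in the targeting subset (no followers)")
  out <- predictions
  if (fluctuation == "logistic") {
    p_b <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    sol <- solve_fluctuation(qlogis(p_b), y, w)
    out[idx] <- plogis(qlogis(p_b) + sol$epsilon)
    eps <- sol$epsilon
  } else {
    eps <- weighted.mean(y - p, w)
    out[idx] <- p + eps
  }
  resid <- weighted.mean(y - out[idx], w)
  list(predictions = out, epsilon = eps, score = resid)
}

#' Longitudinal TMLE estimate of E(Y^k)
#'
#' Targeted maximum likelihood estimation for the mean outcome under the
#' strategy "initiate at `k` unless delivered". The algorithm runs the same
#' backward outcome regressions as [gcomp_estimate()], but after each
#' regression it fluctuates only the random components — the predictions
#' for subjects not yet delivered — with a weighted intercept-only logistic
#' update (weights `w^k(t)` from [weight_trajectory()]), and reintegrates
#' the known outcomes of delivered subjects before the next step. The mean
#' of the final updated values over all subjects is the estimate. The
#' estimator is doubly robust: it is consistent if either the treatment
#' models or the outcome regressions are.
#'
#' Continuous outcomes are affinely scaled into the unit interval
#' ([bound_continuous_outcome()]) so the logistic fluctuation applies, and
#' the estimate is back-transformed.
#'
#' @param cohort A `preg_cohort`.
#' @param k Strategy start time, in `1..K+1`.
#' @param treatment_learner,prob_floor Passed to [fit_treatment_models()].
#' @param outcome_learner Outcome-step learner (default `"logistic"` on the
#'   scaled outcome).
#' @param models Optional pre-fitted `treatment_models`.
#' @param strict Passed to [fit_outcome_step()].
#' @param scale_delta Boundary shrinkage for continuous outcomes.
#' @param fluctuation `"logistic"` (default) or `"linear"`.
#' @return A `gest_estimate`; diagnostics record, per backward step, the
#'   fluctuation intercept, the post-update weighted residual mean, and the
#'   update-subset size.
#' @export
tmle_estimate <- function(cohort, k, treatment_learner = "logistic",
                          outcome_learner = "logistic", models = NULL,
                          prob_floor = 0.001, strict = FALSE,
                          scale_delta = 0.005,
                          fluctuation = c("logistic", "linear")) {
  check_cohort(cohort)
  fluctuation <- match.arg(fluctuation)
  K <- cohort$K

  scaling <- NULL
  y_work <- cohort$Y
  if (any(cohort$Y < 0 | cohort$Y > 1)) {
    scaling <- bound_continuous_outcome(cohort$Y, delta = scale_delta)
    y_work <- scaling$scaled
  }
  work <- cohort
  work$Y <- y_work

  models <- models %||% fit_treatment_models(cohort, treatment_learner,
                                             prob_floor)
  wt <- weight_trajectory(models, cohort, k)

  values <- y_work
  steps <- vector("list", K)
  for (t in seq(K, 1)) {
    step <- fit_outcome_step(values, work, t, k, outcome_learner, strict)
    upd <- tmle_targeting_step(
      predictions = replace(values, step$subset, step$predictions),
      pseudo_outcome = values,
      weights = wt$weights[, t],
      update_subset = step$subset,
      fluctuation = fluctuation
    )
    values <- replace(y_work, step$subset, upd$predictions[step$subset])
    steps[[t]] <- list(t = t, epsilon = upd$epsilon, score = upd$score,
                       n_update = length(step$subset), n_fit = step$n_fit)
  }
  est <- mean(values)
  if (!is.null(scaling)) est <- scaling$to_original(est)

  new_gest_estimate(
    "tmle", k, est,
    diagnostics = c(
      list(n = cohort$n, steps = steps,
           epsilons = vapply(steps, `[[`, numeric(1), "epsilon"),
           scores = vapply(steps, `[[`, numeric(1), "score")),
      weight_diagnostics(wt$weights[, K], wt$S[, K])
    )
  )
}
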