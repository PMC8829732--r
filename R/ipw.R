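#' Per-time probability of following a strategy
#'
#' Returns, for every subject, the conditional probability of continuing to
#' follow the strategy "initiate at `k` unless delivered" at time `t`, given
#' past adherence. For `t < k` this is the probability of remaining
#' untreated; for `t = k`, the probability of initiating; for `t > k`, or
#' once delivery has occurred (`D(t-1) = 1`), following the strategy is
#' automatic and the probability is one.
#'
#' @param models A `treatment_models` object.
#' @param cohort The `preg_cohort` the models were fitted on.
#' @param k Strategy start time, in `1..K+1`.
#' @param t Time, in `1..K`.
#' @return Numeric vector of probabilities over subjects.
#' @export
strategy_probability <- function(models, cohort, k, t) {
  check_cohort(cohort)
  p <- rep(1, cohort$n)
  if (t > k) return(p)
  # the conditional is defined given past adherence: undelivered at t-1 and
  # not initiated before t; subjects who already broke the strategy keep a
  # neutral factor of one (their weight is zeroed by S^k anyway)
  idx <- which(cohort$T_D >= t & at_risk_of_initiation(cohort, t))
  if (length(idx) == 0) return(p)
  p_init <- predict_initiation_prob(models, cohort, t, idx)
  p[idx] <- if (t == k) p_init else 1 - p_init
  p
}

#' Cumulative inverse-probability weights for one strategy
#'
#' Computes `w^k(t) = S^k(t) / prod_{l <= t} P(S^k(l) = 1 | past)`. Subjects
#' whose history is incompatible with the strategy get weight zero; factors
#' after delivery or after the start time `k` equal one, so weights are
#' constant in `t` from then on.
#'
#' @param probabilities An `n x K` matrix whose column `t` is
#'   [strategy_probability()] at time `t`.
#' @param S An `n x K` matrix of strategy-adherence indicators `S^k(t)`.
#' @return An `n x K` matrix of weights.
#' @export
cumulative_weights <- function(probabilities, S) {
  if (!all(dim(probabilities) == dim(S))) {
    abort("probabilities and adherence indicators must have the same shape")
  }
  cum <- probabilities
  if (ncol(cum) > 1) {
    for (t in 2:ncol(cum)) cum[, t] <- cum[, t - 1] * cum[, t]
  }
  if (any(S == 1 & cum <= 0)) {
    abort("positivity violation: a strategy follower has cumulative strategy probability 0")
  }
  W <- matrix(0, nrow(S), ncol(S))
  W[S == 1] <- 1 / cum[S == 1]
  W
}

#' Weight trajectory for one strategy
#'
#' Convenience wrapper assembling per-time strategy probabilities, adherence
#' indicators, and cumulative weights for strategy `k`.
#'
#' @inheritParams strategy_probability
#' @return A list with matrices `probabilities`, `S`, `weights` (all
#'   `n x K`) and the strategy `k`.
#' @export
weight_trajectory <- function(models, cohort, k) {
  K <- cohort$K
  S <- vapply(seq_len(K), function(t) strategy_indicator(cohort, k, t),
              integer(cohort$n))
  P <- vapply(seq_len(K), function(t) strategy_probability(models, cohort, k, t),
              numeric(cohort$n))
  if (cohort$n == 1) { S <- matrix(S, 1); P <- matrix(P, 1) }
  list(k = k, probabilities = P, S = S, weights = cumulative_weights(P, S))
}

weight_diagnostics <- function(w_final, S_final) {
  wpos <- w_final[S_final == 1]
  list(
    n_followers = sum(S_final == 1),
    max_weight = if (length(wpos)) max(wpos) else NA_real_,
    mean_weight = if (length(wpos)) mean(wpos) else NA_real_,
    ess = if (length(wpos)) sum(wpos)^2 / sum(wpos^2) else NA_real_
  )
}

#' Treatment-strategy IPW estimate of E(Y^k)
#'
#' Weighted mean of the outcome over subjects who followed strategy `k`
#' through the final time point, with weights the cumulative inverse
#' probabilities of following (equivalently, the intercept of a weighted
#' intercept-only linear regression of the outcome).
#'
#' @param cohort A `preg_cohort`.
#' @param k Strategy start time, in `1..K+1`.
#' @param models Optional pre-fitted `treatment_models` (fitted if `NULL`).
#' @param learner,prob_floor Passed to [fit_treatment_models()] when
#'   `models` is `NULL`.
#' @param truncate_at Optional percentile (in (0, 1]) at which follower
#'   weights are truncated; `NULL` (default) leaves weights untouched.
#' @return A `gest_estimate`.
#' @export
ipw_estimate <- function(cohort, k, models = NULL, learner = "logistic",
                         prob_floor = 0.001, truncate_at = NULL) {
  check_cohort(cohort)
  models <- models %||% fit_treatment_models(cohort, learner, prob_floor)
  wt <- weight_trajectory(models, cohort, k)
  K <- cohort$K
  w <- wt$weights[, K]
  S <- wt$S[, K]
  if (sum(S) == 0) {
    abort(paste0("no subject follows strategy k = ", k,
                 " through time K; E(Y^", k, ") is not estimable"))
  }
  if (!is.null(truncate_at)) {
    cap <- quantile(w[S == 1], probs = truncate_at, names = FALSE)
    w <- pmin(w, cap)
  }
  est <- weighted.mean(cohort$Y[S == 1], w[S == 1])
  diag <- c(list(n = cohort$n, n_at_risk = models$n_at_risk,
                 truncate_at = truncate_at),
            weight_diagnostics(w, S))
  new_gest_estimate("ipw", k, est, diagnostics = diag)
}

#' Joint IPW marginal structural model over all strategies
#'
#' Stacks one record per (subject, strategy the subject followed through
#' `K`) with that strategy's final weight, and fits a weighted linear
#' regression of the outcome on strategy indicators. Because one observed
#' history can follow several strategies at once, the stacked data realize
#' the summed-weight estimating equations of the marginal structural model.
#' With a model saturated in strategy (the default and only option), the
#' fitted per-strategy means coincide with the strategy-wise
#' [ipw_estimate()] values.
#'
#' @param cohort A `preg_cohort`.
#' @param ks Strategies to include (default `2..K+1`).
#' @inheritParams ipw_estimate
#' @return A list with `means` (tibble of per-strategy fitted means),
#'   `contrasts` (tibble of adjacent contrasts), and `fit` (the `lm` fit on
#'   the stacked data).
#' @export
ipw_msm <- function(cohort, ks = NULL, models = NULL, learner = "logistic",
                    prob_floor = 0.001) {
  check_cohort(cohort)
  ks <- ks %||% seq(2L, cohort$K + 1L)
  models <- models %||% fit_treatment_models(cohort, learner, prob_floor)
  stacked <- purrr::map_dfr(ks, function(k) {
    wt <- weight_trajectory(models, cohort, k)
    S <- wt$S[, cohort$K]
    if (sum(S) == 0) {
      abort(paste0("no subject follows strategy k = ", k, " through time K"))
    }
    tibble::tibble(
      subject_id = cohort$subject_id[S == 1],
      k = k,
      Y = cohort$Y[S == 1],
      w = wt$weights[S == 1, cohort$K]
    )
  })
  fit <- lm(Y ~ 0 + factor(k), data = stacked, weights = stacked$w)
  means <- tibble::tibble(
    k = ks,
    estimate = unname(fit$coefficients[paste0("factor(k)", ks)])
  )
  contrasts <- tibble::tibble(
    k1 = ks[-length(ks)], k2 = ks[-1],
    estimate = means$estimate[-length(ks)] - means$estimate[-1]
  )
  list(means = means, contrasts = contrasts, fit = fit)
}
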