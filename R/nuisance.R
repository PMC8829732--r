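#' Fit per-time treatment-initiation models
#'
#' Fits, for each time `t = 1..K`, a model for the conditional probability
#' of initiating exposure at `t`,
#' `P(A(t) = 1 | W-history(t), no initiation by t-1, undelivered at t-1)`.
#' Each model is fitted only on the at-risk subset: subjects undelivered at
#' `t - 1` who have not yet initiated. These are the only probabilities the
#' strategy-weighting machinery needs, because once a subject has delivered
#' (or once `t` is past the strategy's start time) the probability of
#' continuing to follow the strategy is one by construction.
#'
#' @param cohort A `preg_cohort`.
#' @param learner `"saturated"` (exact cell proportions over the discrete
#'   covariate history), `"logistic"` (main-terms logistic regression on the
#'   covariate history, the default), `"intercept"` (overall initiation
#'   proportion, ignoring covariates), or a plugin
#'   `function(y, X, newX)` returning probabilities.
#' @param prob_floor Predicted probabilities are clipped to
#'   `[prob_floor, 1 - prob_floor]` for weight stability. Default 0.001;
#'   set 0 to disable (useful with saturated learners in exact tests).
#' @return A `treatment_models` object: one fitted model per time plus the
#'   per-time at-risk sample sizes.
#' @export
fit_treatment_models <- function(cohort, learner = "logistic",
                                 prob_floor = 0.001) {
  check_cohort(cohort)
  check_learner(learner)
  K <- cohort$K
  fits <- vector("list", K)
  n_at_risk <- integer(K)
  for (t in seq_len(K)) {
    idx <- which(at_risk_of_initiation(cohort, t))
    n_at_risk[t] <- length(idx)
    if (length(idx) == 0 && !is.function(learner)) {
      abort(paste0("no at-risk subjects at time ", t,
                   " (all delivered or already initiated)"))
    }
    y <- cohort$A[idx, t]
    if (identical(learner, "saturated") && (sum(y) == 0 || sum(y) == length(y))) {
      abort(paste0("positivity violation at time ", t, ": ",
                   if (sum(y) == 0) "no at-risk subject initiates"
                   else "every at-risk subject initiates"))
    }
    X <- history_design(cohort, t, idx)
    fits[[t]] <- fit_mean_learner(y, X, learner)
  }
  structure(
    list(fits = fits, n_at_risk = n_at_risk, learner = learner,
         prob_floor = prob_floor, K = K, covariates = cohort$covariates),
    class = "treatment_models"
  )
}

#' @export
print.treatment_models <- function(x, ...) {
  cat("<treatment_models> K =", x$K, "times, learner:",
      if (is.function(x$learner)) "plugin" else x$learner, "\n")
  cat("  at-risk n per time:", paste(x$n_at_risk, collapse = ", "), "\n")
  invisible(x)
}

# subjects undelivered at t-1 with no initiation before t
at_risk_of_initiation <- function(cohort, t) {
  undelivered <- cohort$T_D >= t
  not_initiated <- is.na(cohort$T_A) | cohort$T_A >= t
  undelivered & not_initiated
}

# covariate-history design matrix W(1), ..., W(t) for the given subjects
history_design <- function(cohort, t, idx) {
  cols <- lapply(cohort$covariates, function(wname) {
    m <- cohort$W[[wname]][idx, seq_len(t), drop = FALSE]
    colnames(m) <- paste0(wname, ".", seq_len(t))
    m
  })
  do.call(cbind, cols)
}

# exposure-history design A(1), ..., A(j) with given values
exposure_design <- function(Avals, j, prefix = "A") {
  colnames(Avals) <- paste0(prefix, ".", seq_len(j))
  Avals
}

# P(A(t) = 1 | W-history(t)) for the given subjects (must be undelivered
# at t-1), clipped to the configured floor
predict_initiation_prob <- function(models, cohort, t, idx) {
  if (any(cohort$T_D[idx] < t)) {
    abort("initiation probability requested after delivery")
  }
  X <- history_design(cohort, t, idx)
  p <- predict_mean_learner(models$fits[[t]], X)
  eps <- models$prob_floor
  pmin(pmax(p, eps), 1 - eps)
}

#' Fit one backward outcome-regression step
#'
#' Regresses a pseudo-outcome (the previous iterate of the nested
#' conditional expectations) on the covariate and exposure history through
#' time `t`, among subjects undelivered at `t - 1`, and predicts for those
#' same subjects with the exposure history set to the values implied by
#' strategy `k`: no exposure before `k`, exposure at `k` if `k <= t`.
#' Post-initiation exposure times never enter the conditioning set of the
#' intent-to-treat recursion.
#'
#' @param pseudo_outcome Numeric vector over all subjects (only the
#'   undelivered-at-`t-1` entries are used for fitting).
#' @param cohort A `preg_cohort`.
#' @param t Time of the step, in `1..K`.
#' @param k Strategy start time, in `1..K+1`.
#' @param learner As in [fit_treatment_models()]; `"linear"` is also
#'   accepted for continuous pseudo-outcomes.
#' @param strict If `TRUE`, fit only on subjects whose observed exposure
#'   history is itself consistent with strategy `k` through `t` (the
#'   alternative reading of the conditioning set); the default fits on all
#'   undelivered subjects and intervenes on the exposure columns at
#'   prediction time.
#' @return An `outcome_step` object with elements `fit`, `predictions`
#'   (vector over the undelivered subjects), `subset` (their indices),
#'   `n_fit`, `t`, `k`.
#' @export
fit_outcome_step <- function(pseudo_outcome, cohort, t, k,
                             learner = "logistic", strict = FALSE) {
  check_cohort(cohort)
  check_learner(learner)
  undelivered <- which(cohort$T_D >= t)
  if (length(undelivered) == 0) {
    abort(paste0("outcome step (t = ", t, ", k = ", k,
                 "): no undelivered subjects to fit on"))
  }
  fit_idx <- undelivered
  if (strict) {
    consistent <- if (t < k) {
      is.na(cohort$T_A) | cohort$T_A > t
    } else {
      !is.na(cohort$T_A) & cohort$T_A == k
    }
    fit_idx <- undelivered[consistent[undelivered]]
    if (length(fit_idx) == 0) {
      abort(paste0("outcome step (t = ", t, ", k = ", k,
                   "): no strategy-consistent undelivered subjects"))
    }
  }
  j <- min(t, k)
  Xw_fit <- history_design(cohort, t, fit_idx)
  Xa_fit <- if (j >= 1 && k <= cohort$K) {
    exposure_design(cohort$A[fit_idx, seq_len(j), drop = FALSE], j)
  } else if (k > cohort$K) {
    # never-initiate: condition on remaining unexposed through t
    exposure_design(cohort$A[fit_idx, seq_len(t), drop = FALSE], t)
  }
  X_fit <- cbind(Xw_fit, Xa_fit)
  y <- pseudo_outcome[fit_idx]
  if (anyNA(y)) abort("pseudo-outcome contains missing values in the fitting subset")
  fit <- fit_mean_learner(y, X_fit, learner)

  Xw_new <- history_design(cohort, t, undelivered)
  ja <- if (k > cohort$K) t else j
  Anew <- matrix(as.numeric(seq_len(ja) == k), nrow = length(undelivered),
                 ncol = ja, byrow = TRUE)
  X_new <- cbind(Xw_new, exposure_design(Anew, ja))
  preds <- predict_mean_learner(fit, X_new)

  structure(
    list(fit = fit, predictions = preds, subset = undelivered,
         n_fit = length(fit_idx), t = t, k = k, strict = strict),
    class = "outcome_step"
  )
}

# default outcome learner: probability-scale logistic when the outcome is
# bounded in [0,1], else ordinary least squares
default_outcome_learner <- function(y) {
  if (all(y >= 0 & y <= 1)) "logistic" else "linear"
}
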