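#' Closed-form expectations for the two-arm toy initiation trial
#'
#' Analytic calculator for the illustrative randomized trial in which
#' participants are randomized at conception to "initiate medication at the
#' late time point" versus "never initiate", a fraction of deliveries occur
#' before the initiation time (so those assigned to treat can never receive
#' it), and the medication has no biological effect on the outcome. The
#' naive per-protocol analysis pools every early delivery into the
#' unexposed group — regardless of assignment — and therefore manufactures
#' a spurious protective effect; the intent-to-treat comparison recovers
#' the correct null.
#'
#' @param p_early Probability of delivery before the initiation time.
#' @param risk_early Outcome probability for early deliveries.
#' @param risk_full Outcome probability for full-term deliveries.
#' @param allocation Fraction randomized to the treated arm (default 0.5).
#' @return A tibble with one row per analysis group
#'   (`per_protocol` exposed/unexposed, `itt` treated/control) and columns
#'   `p_group` (group share of the cohort), `p_early_delivery`,
#'   `p_full_term`, `p_outcome`.
#' @examples
#' toy_trial_expectations(0.10, 0.5, 0.05)
#' @export
toy_trial_expectations <- function(p_early, risk_early, risk_full,
                                   allocation = 0.5) {
  probs <- c(p_early, risk_early, risk_full, allocation)
  if (any(probs < 0 | probs > 1)) abort("all inputs must be probabilities in [0, 1]")

  # per-protocol: exposed = treated full-terms only; unexposed = all early
  # deliveries (whatever their assignment) + control-arm full-terms
  p_exposed <- allocation * (1 - p_early)
  p_unexposed <- p_early + (1 - allocation) * (1 - p_early)
  if (p_exposed == 0) {
    warn("exposed per-protocol group is empty (p_early = 1 or allocation = 0)")
  }
  early_un <- p_early / p_unexposed
  pp <- tibble::tibble(
    analysis = "per_protocol",
    group = c("exposed", "unexposed"),
    p_group = c(p_exposed, p_unexposed),
    p_early_delivery = c(0, early_un),
    p_full_term = c(1, 1 - early_un),
    p_outcome = c(risk_full,
                  early_un * risk_early + (1 - early_un) * risk_full)
  )
  if (p_exposed == 0) pp$p_outcome[1] <- NA_real_

  # ITT: arms pool by assignment; composition identical by randomization
  itt_outcome <- p_early * risk_early + (1 - p_early) * risk_full
  itt <- tibble::tibble(
    analysis = "itt",
    group = c("treated", "control"),
    p_group = c(allocation, 1 - allocation),
    p_early_delivery = p_early,
    p_full_term = 1 - p_early,
    p_outcome = itt_outcome
  )
  dplyr::bind_rows(pp, itt)
}

#' Standard full-term-censored IPW (biased comparator)
#'
#' The conventional IPW implementation this package's strategy weighting is
#' designed to replace: restrict to subjects still undelivered entering the
#' final interval (censor everyone who delivered early), weight each by the
#' inverse cumulative probability of their observed exposure path, and
#' contrast groups defined by observed initiation time. Censoring on
#' delivery blocks the effect mediated by delivery time and, when delivery
#' and outcome share an unmeasured cause, opens a collider path — both
#' sources of bias for the total effect.
#'
#' @param cohort A `preg_cohort`.
#' @param ks Initiation times to compare (default `2..K+1`, with `K+1`
#'   meaning never initiated).
#' @inheritParams ipw_estimate
#' @return A list with `means` (tibble of per-initiation-time weighted
#'   means among full-term deliveries) and `contrasts` (adjacent
#'   differences); each carries `n_group` diagnostics.
#' @export
standard_ipw_estimate <- function(cohort, ks = NULL, models = NULL,
                                  learner = "logistic", prob_floor = 0.001) {
  check_cohort(cohort)
  K <- cohort$K
  ks <- ks %||% seq(2L, K + 1L)
  models <- models %||% fit_treatment_models(cohort, learner, prob_floor)

  full_term <- which(cohort$T_D == K)   # D(K-1) = 0, i.e. not censored
  init_time <- ifelse(is.na(cohort$T_A), K + 1L, cohort$T_A)

  # inverse probability of the observed exposure path; post-initiation
  # person-time contributes probability one (sustained adherence)
  w <- rep(0, cohort$n)
  if (length(full_term) > 0) {
    cum <- rep(1, length(full_term))
    ti <- init_time[full_term]
    for (t in seq_len(K)) {
      need <- which(ti >= t)           # post-initiation factors equal one
      if (length(need) == 0) next
      p_init <- predict_initiation_prob(models, cohort, t, full_term[need])
      cum[need] <- cum[need] * ifelse(t == ti[need], p_init, 1 - p_init)
    }
    w[full_term] <- 1 / cum
  }

  means <- purrr::map_dfr(ks, function(k) {
    grp <- intersect(full_term, which(init_time == k))
    if (length(grp) == 0) {
      abort(paste0("no full-term subject initiated at time ", k))
    }
    tibble::tibble(k = k,
                   estimate = weighted.mean(cohort$Y[grp], w[grp]),
                   n_group = length(grp))
  })
  contrasts <- tibble::tibble(
    k1 = ks[-length(ks)], k2 = ks[-1],
    estimate = means$estimate[-length(ks)] - means$estimate[-1]
  )
  list(means = means, contrasts = contrasts,
       n_censored = cohort$n - length(full_term))
}

#' Naive zero-filled regression (biased comparator)
#'
#' Single linear model of the outcome on exposure and covariates at all
#' time points, with every post-delivery exposure and covariate value
#' assigned zero rather than treated as undefined — the analysis a
#' standard regression workflow would produce if delivery interruption
#' were ignored. Collinear terms are dropped with a message.
#'
#' @param cohort A `preg_cohort`.
#' @return A tibble of the per-time exposure coefficients
#'   (`term`, `time`, `estimate`), with the full `lm` fit as attribute
#'   `"fit"`.
#' @export
naive_regression_estimate <- function(cohort) {
  check_cohort(cohort)
  K <- cohort$K
  zero_fill <- function(m) { m[is.na(m)] <- 0; m }
  A0 <- zero_fill(cohort$A)
  colnames(A0) <- paste0("A.", seq_len(K))
  Wmats <- lapply(cohort$covariates, function(wname) {
    m <- zero_fill(cohort$W[[wname]])
    colnames(m) <- paste0(wname, ".", seq_len(K))
    m
  })
  df <- as.data.frame(cbind(A0, do.call(cbind, Wmats)))
  df$Y <- cohort$Y
  fit <- lm(Y ~ ., data = df)
  dropped <- names(which(is.na(fit$coefficients)))
  if (length(dropped) > 0) {
    inform(paste0("collinear terms dropped: ", paste(dropped, collapse = ", ")))
  }
  out <- tibble::tibble(
    term = paste0("A.", seq_len(K)),
    time = seq_len(K),
    estimate = unname(fit$coefficients[paste0("A.", seq_len(K))])
  )
  attr(out, "fit") <- fit
  out
}
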