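#' Repeated-sampling evaluation of the estimators
#'
#' Runs the full simulation experiment: for each scenario, computes the
#' true adjacent strategy contrasts with the forced-assignment oracle, then
#' repeatedly draws cohorts, applies the requested estimators to the three
#' adjacent contrasts `E(Y^2)-E(Y^3)`, `E(Y^3)-E(Y^4)`, `E(Y^4)-E(Y^5)`,
#' and summarises bias (mean estimate minus truth) and Monte-Carlo standard
#' error (the standard deviation of the estimates across repetitions).
#'
#' @param scenarios Scenario ids to run (default `1:4`).
#' @param reps Number of repetitions per scenario.
#' @param n Cohort size per repetition.
#' @param estimators Character subset of
#'   `c("ipw", "gcomp", "tmle", "standard_ipw")`.
#' @param seed Integer seed governing the whole study (truth oracle and
#'   cohort draws use derived sub-seeds).
#' @param truth_n Oracle simulation size (default `1e6`).
#' @param coefs Structural-coefficient overrides passed to
#'   [scenario_spec()].
#' @param learner Treatment/outcome learner for the estimators.
#' @param outcome_learner Outcome learner override (defaults to `learner`).
#' @return A `gest_sim_study` list: `summary` (tibble: scenario, method,
#'   k1, k2, truth, bias, mc_se, n_ok), `results` (per-repetition
#'   estimates), `truth`, and the study settings.
#' @export
run_simulation_study <- function(scenarios = 1:4, reps = 250, n = 1000,
                                 estimators = c("ipw", "gcomp", "tmle",
                                                "standard_ipw"),
                                 seed = 1, truth_n = 1e6, coefs = list(),
                                 learner = "logistic",
                                 outcome_learner = NULL) {
  estimators <- match.arg(estimators, several.ok = TRUE)
  outcome_learner <- outcome_learner %||% learner
  results <- vector("list", length(scenarios))
  truths <- vector("list", length(scenarios))
  n_failed <- 0L

  for (si in seq_along(scenarios)) {
    sc <- scenarios[si]
    spec <- scenario_spec(sc, n = n, coefs = coefs)
    truths[[si]] <- counterfactual_truth(
      spec, ks = 2:5, n = truth_n, seed = derive_seed(seed, 1000 + sc)
    )$contrasts |>
      dplyr::mutate(scenario = sc, .before = 1)

    reps_out <- vector("list", reps)
    for (r in seq_len(reps)) {
      cohort <- simulate_cohort(spec, seed = derive_seed(seed, sc * 1e5 + r))
      est <- tryCatch(
        estimate_all_contrasts(cohort, estimators, learner, outcome_learner),
        error = function(e) NULL
      )
      if (is.null(est)) { n_failed <- n_failed + 1L; next }
      reps_out[[r]] <- dplyr::mutate(est, scenario = sc, rep = r, .before = 1)
    }
    results[[si]] <- dplyr::bind_rows(reps_out)
  }

  results <- dplyr::bind_rows(results)
  truth <- dplyr::bind_rows(truths)
  summary <- results |>
    dplyr::left_join(truth[c("scenario", "k1", "k2", "value")],
                     by = c("scenario", "k1", "k2")) |>
    dplyr::group_by(.data$scenario, .data$method, .data$k1, .data$k2) |>
    dplyr::summarise(
      truth = .data$value[1],
      bias = mean(.data$estimate) - .data$value[1],
      mc_se = sd(.data$estimate),
      n_ok = dplyr::n(),
      .groups = "drop"
    )
  structure(
    list(summary = summary, results = results, truth = truth,
         reps = reps, n = n, seed = seed, n_failed = n_failed),
    class = "gest_sim_study"
  )
}

# all three adjacent contrasts for the requested estimators on one cohort;
# treatment models are shared across strategies and estimators
estimate_all_contrasts <- function(cohort, estimators, learner,
                                   outcome_learner) {
  ks <- 2:5
  models <- if (any(estimators %in% c("ipw", "tmle", "standard_ipw"))) {
    fit_treatment_models(cohort, learner)
  }
  out <- list()
  adj <- function(means) {
    tibble::tibble(k1 = ks[-4], k2 = ks[-1],
                   estimate = means[-4] - means[-1])
  }
  if ("ipw" %in% estimators) {
    m <- vapply(ks, function(k) ipw_estimate(cohort, k, models = models)$estimate,
                numeric(1))
    out$ipw <- adj(m)
  }
  if ("gcomp" %in% estimators) {
    m <- vapply(ks, function(k) gcomp_estimate(cohort, k,
                                               learner = outcome_learner)$estimate,
                numeric(1))
    out$gcomp <- adj(m)
  }
  if ("tmle" %in% estimators) {
    m <- vapply(ks, function(k) {
      tmle_estimate(cohort, k, models = models,
                    outcome_learner = outcome_learner)$estimate
    }, numeric(1))
    out$tmle <- adj(m)
  }
  if ("standard_ipw" %in% estimators) {
    out$standard_ipw <- standard_ipw_estimate(cohort, ks, models = models)$contrasts
  }
  dplyr::bind_rows(out, .id = "method")
}

# deterministic small sub-seed from a master seed and a stream index
derive_seed <- function(seed, stream) {
  (as.integer(seed) * 69069L + as.integer(stream)) %% 2147483587L
}

#' @export
print.gest_sim_study <- function(x, ...) {
  cat("<gest_sim_study>", x$reps, "repetitions, n =", x$n, "per cohort")
  if (x$n_failed > 0) cat(" (", x$n_failed, " failed repetitions)", sep = "")
  cat("\n")
  print(x$summary, n = Inf)
  invisible(x)
}

#' @export
tidy.gest_sim_study <- function(x, ...) x$summary

#' Bias plot for a simulation study
#'
#' @param object A `gest_sim_study`.
#' @param ... Unused.
#' @return A ggplot: bias with +-2 Monte-Carlo-standard-error-of-the-mean
#'   bars, by contrast, method, and scenario.
#' @exportS3Method ggplot2::autoplot
autoplot.gest_sim_study <- function(object, ...) {
  df <- object$summary |>
    dplyr::mutate(
      contrast = paste0("E(Y^", .data$k1, ") - E(Y^", .data$k2, ")"),
      se_mean = .data$mc_se / sqrt(.data$n_ok)
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$contrast, y = .data$bias,
                                   colour = .data$method)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$bias - 2 * .data$se_mean,
                   ymax = .data$bias + 2 * .data$se_mean),
      position = ggplot2::position_dodge(width = 0.5)
    ) +
    ggplot2::facet_wrap(~ .data$scenario, labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = "bias (estimate - truth)", colour = "method") +
    ggplot2::theme_minimal()
}
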