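#' Contrast two strategy-mean estimates
#'
#' Difference of two point estimates of `E(Y^k)` computed on the same
#' cohort with the same method. When both carry bootstrap replicates from
#' the same resampling plan (as produced by [bootstrap_ci()], which
#' evaluates all requested quantities on each resampled cohort), the
#' confidence interval is taken from the paired replicate differences —
#' never by differencing the two marginal intervals.
#'
#' @param x1,x2 `gest_estimate` objects for strategies `k1` and `k2`.
#' @param level Confidence level used when replicates are available.
#' @return A `gest_estimate` for the contrast `E(Y^k1) - E(Y^k2)`.
#' @export
contrast <- function(x1, x2, level = 0.95) {
  if (!inherits(x1, "gest_estimate") || !inherits(x2, "gest_estimate")) {
    abort("contrast() expects two gest_estimate objects")
  }
  if (!identical(x1$method, x2$method)) {
    abort("contrasted estimates must come from the same method")
  }
  if (!identical(x1$diagnostics$n, x2$diagnostics$n)) {
    abort("contrasted estimates must come from the same cohort")
  }
  est <- x1$estimate - x2$estimate
  ci <- c(NA_real_, NA_real_); B <- 0L; reps <- NULL; lev <- NA_real_
  if (!is.null(x1$replicates) && !is.null(x2$replicates)) {
    if (length(x1$replicates) != length(x2$replicates)) {
      abort("replicates are not paired (different bootstrap plans)")
    }
    reps <- x1$replicates - x2$replicates
    ci <- percentile_ci(reps, level)
    B <- length(reps); lev <- level
  }
  new_gest_estimate(x1$method, x1$k1, est, k2 = x2$k1, ci = ci, level = lev,
                    B = B, replicates = reps,
                    diagnostics = list(n = x1$diagnostics$n))
}

percentile_ci <- function(reps, level) {
  alpha <- (1 - level) / 2
  unname(quantile(reps, c(alpha, 1 - alpha), type = 7))
}

#' Nonparametric bootstrap over subjects
#'
#' Resamples subjects (entire trajectories, never individual rows) with
#' replacement, re-runs an estimator closure end to end on each resampled
#' cohort — so all nuisance models are refitted inside each replicate —
#' and returns percentile confidence intervals. Replicates in which the
#' estimator fails (for example through an empty positivity cell) are
#' excluded and counted; more than 20% failures aborts, since the
#' estimator is evidently unstable on this cohort.
#'
#' @param cohort A `preg_cohort`.
#' @param statistic A function `cohort -> named numeric vector` computing
#'   every quantity an interval is wanted for (point estimates, contrasts).
#' @param B Number of bootstrap replicates (`B = 1` yields the degenerate
#'   interval equal to the single replicate).
#' @param level Confidence level (default 0.95).
#' @param seed Optional integer seed for the resampling stream.
#' @param interval `"percentile"` (default) or `"normal"` (point estimate
#'   +- z * replicate standard deviation).
#' @return A `gest_bootstrap` list: `ci` (tibble: term, estimate, ci_lo,
#'   ci_hi, level, B), `replicates` (B x p matrix), `n_failed`.
#' @export
bootstrap_ci <- function(cohort, statistic, B = 1000, level = 0.95,
                         seed = NULL, interval = c("percentile", "normal")) {
  check_cohort(cohort)
  interval <- match.arg(interval)
  if (B < 1) abort("B must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  point <- statistic(cohort)
  if (is.null(names(point))) names(point) <- paste0("stat", seq_along(point))

  reps <- matrix(NA_real_, B, length(point),
                 dimnames = list(NULL, names(point)))
  n_failed <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(cohort$n, cohort$n, replace = TRUE)
    val <- tryCatch(statistic(resample_cohort(cohort, idx)),
                    error = function(e) NULL)
    if (is.null(val)) n_failed <- n_failed + 1L else reps[b, ] <- val
  }
  if (n_failed > 0.2 * B) {
    abort(paste0("bootstrap unstable: ", n_failed, " of ", B,
                 " replicates failed"))
  }
  ok <- reps[!is.na(reps[, 1]), , drop = FALSE]
  ci <- purrr::map_dfr(seq_along(point), function(j) {
    lims <- if (interval == "percentile") {
      percentile_ci(ok[, j], level)
    } else {
      z <- stats::qnorm(1 - (1 - level) / 2)
      point[j] + c(-1, 1) * z * sd(ok[, j])
    }
    tibble::tibble(term = names(point)[j], estimate = unname(point[j]),
                   ci_lo = lims[1], ci_hi = lims[2], level = level,
                   B = nrow(ok))
  })
  structure(list(ci = ci, replicates = ok, n_failed = n_failed,
                 level = level, B = B, interval = interval),
            class = "gest_bootstrap")
}

#' @export
print.gest_bootstrap <- function(x, ...) {
  cat("<gest_bootstrap> B =", x$B, "replicates")
  if (x$n_failed > 0) cat(" (", x$n_failed, " failed)", sep = "")
  cat(", ", x$interval, " intervals\n", sep = "")
  print(x$ci)
  invisible(x)
}

#' Estimate strategy means and adjacent contrasts with bootstrap intervals
#'
#' End-to-end convenience wrapper: estimates `E(Y^k)` for each requested
#' strategy with the chosen method, forms adjacent contrasts, and (when
#' `B > 0`) attaches paired percentile bootstrap intervals in which all
#' nuisance models are refitted per replicate.
#'
#' @param cohort A `preg_cohort`.
#' @param method `"ipw"`, `"gcomp"`, or `"tmle"`.
#' @param ks Strategies (default `2..K+1`).
#' @param B Bootstrap replicates (0 = no intervals).
#' @param level Confidence level.
#' @param seed Seed for the bootstrap stream.
#' @param ... Passed to the underlying estimator (outcome learner options
#'   and the like). Treatment models are fitted once per (re)sampled cohort
#'   with the default main-terms logistic learner and shared across
#'   strategies.
#' @return A tibble of results (one row per strategy mean and per adjacent
#'   contrast) with the standard columns
#'   `method, k1, k2, estimate, ci_lo, ci_hi, level, B`.
#' @export
estimate_itt <- function(cohort, method = c("ipw", "gcomp", "tmle"),
                         ks = NULL, B = 0, level = 0.95, seed = NULL, ...) {
  check_cohort(cohort)
  method <- match.arg(method)
  ks <- ks %||% seq(2L, cohort$K + 1L)
  # treatment models are strategy-independent: fit once per (re)sampled
  # cohort and share across all ks
  fn <- switch(method,
    ipw = function(ch, k, tm, ...) ipw_estimate(ch, k, models = tm, ...),
    gcomp = function(ch, k, tm, ...) gcomp_estimate(ch, k, ...),
    tmle = function(ch, k, tm, ...) tmle_estimate(ch, k, models = tm, ...)
  )
  statistic <- function(ch) {
    tm <- if (method %in% c("ipw", "tmle")) fit_treatment_models(ch)
    m <- vapply(ks, function(k) fn(ch, k, tm, ...)$estimate, numeric(1))
    names(m) <- paste0("k", ks)
    if (length(ks) > 1) {
      d <- m[-length(m)] - m[-1]
      names(d) <- paste0("k", ks[-length(ks)], "_vs_k", ks[-1])
      m <- c(m, d)
    }
    m
  }
  point <- statistic(cohort)
  if (B > 0) {
    boot <- bootstrap_ci(cohort, statistic, B = B, level = level, seed = seed)
    ci <- boot$ci
  } else {
    ci <- tibble::tibble(term = names(point), estimate = unname(point),
                         ci_lo = NA_real_, ci_hi = NA_real_,
                         level = NA_real_, B = 0L)
  }
  nk <- length(ks)
  out <- dplyr::mutate(
    ci,
    method = method,
    k1 = c(ks, ks[-nk]),
    k2 = c(rep(NA_integer_, nk), ks[-1]),
    .before = 1
  )
  out <- dplyr::select(out, "method", "k1", "k2", "estimate",
                       "ci_lo", "ci_hi", "level", "B")
  class(out) <- c("gest_results", class(out))
  out
}

#' Write a results table to CSV and JSON with a run log
#'
#' @param results A tibble with the standard result columns (as returned
#'   by [estimate_itt()] or [estimate_table()]).
#' @param path Output path stem; writes `<path>.csv`, `<path>.json`, and
#'   `<path>.log`.
#' @param config Optional named list recorded in the log.
#' @return Invisibly, the paths written.
#' @export
report_results <- function(results, path, config = list()) {
  results <- tibble::as_tibble(results)
  needed <- c("method", "k1", "k2", "estimate", "ci_lo", "ci_hi", "level", "B")
  missing_cols <- setdiff(needed, names(results))
  if (length(missing_cols) > 0) {
    abort(paste0("results table is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  csv <- paste0(path, ".csv"); json <- paste0(path, ".json")
  log <- paste0(path, ".log")
  utils::write.csv(results[needed], csv, row.names = FALSE)
  jsonlite::write_json(results[needed], json, digits = NA, na = "null")
  writeLines(c(
    paste0("written: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    paste0("R version: ", R.version.string),
    paste0("gestinit version: ",
           as.character(utils::packageVersion("gestinit"))),
    vapply(names(config), function(nm) {
      paste0(nm, ": ", paste(format(config[[nm]]), collapse = " "))
    }, character(1))
  ), log)
  invisible(c(csv = csv, json = json, log = log))
}

#' Forest plot of strategy estimates and contrasts
#'
#' @param object A `gest_results` tibble from [estimate_itt()].
#' @param ... Unused.
#' @return A ggplot forest plot of estimates with intervals.
#' @exportS3Method ggplot2::autoplot
autoplot.gest_results <- function(object, ...) {
  df <- dplyr::mutate(
    tibble::as_tibble(object),
    label = ifelse(is.na(.data$k2), paste0("E(Y^", .data$k1, ")"),
                   paste0("E(Y^", .data$k1, ") - E(Y^", .data$k2, ")")),
    kind = ifelse(is.na(.data$k2), "strategy mean", "contrast")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_lo, xmax = .data$ci_hi), height = 0.2
    ) +
    ggplot2::facet_wrap(~ .data$kind, scales = "free") +
    ggplot2::labs(x = "estimate", y = NULL) +
    ggplot2::theme_minimal()
}
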