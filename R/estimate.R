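# Result container shared by all estimators: a point estimate of E(Y^k)
# (k2 = NA) or of a contrast E(Y^k1) - E(Y^k2), an optional bootstrap CI,
# and method-specific diagnostics.

new_gest_estimate <- function(method, k1, estimate, k2 = NA_integer_,
                              ci = c(NA_real_, NA_real_), level = NA_real_,
                              B = 0L, diagnostics = list(),
                              replicates = NULL) {
  structure(
    list(method = method, k1 = as.integer(k1), k2 = as.integer(k2),
         estimate = as.numeric(estimate),
         ci_lo = ci[1], ci_hi = ci[2], level = level, B = as.integer(B),
         diagnostics = diagnostics, replicates = replicates),
    class = "gest_estimate"
  )
}

#' @export
print.gest_estimate <- function(x, ...) {
  target <- if (is.na(x$k2)) {
    paste0("E(Y^", x$k1, ")")
  } else {
    paste0("E(Y^", x$k1, ") - E(Y^", x$k2, ")")
  }
  cat("<gest_estimate> ", x$method, " estimate of ", target, ": ",
      format(x$estimate, digits = 4), "\n", sep = "")
  if (!is.na(x$ci_lo)) {
    cat("  ", format(100 * x$level), "% bootstrap CI (B = ", x$B, "): [",
        format(x$ci_lo, digits = 4), ", ", format(x$ci_hi, digits = 4),
        "]\n", sep = "")
  }
  invisible(x)
}

#' Tidy an estimate into a one-row tibble
#'
#' @param x A `gest_estimate`.
#' @param ... Unused.
#' @return A tibble with columns
#'   `method, k1, k2, estimate, ci_lo, ci_hi, level, B`.
#' @export
tidy.gest_estimate <- function(x, ...) {
  tibble::tibble(
    method = x$method, k1 = x$k1, k2 = x$k2, estimate = x$estimate,
    ci_lo = x$ci_lo, ci_hi = x$ci_hi, level = x$level, B = x$B
  )
}

#' One-row summary of estimator diagnostics
#'
#' @param x A `gest_estimate`.
#' @param ... Unused.
#' @return A tibble with the point estimate plus weight/sample-size
#'   diagnostics where the method records them.
#' @export
glance.gest_estimate <- function(x, ...) {
  d <- x$diagnostics
  tibble::tibble(
    method = x$method,
    estimate = x$estimate,
    n = d$n %||% NA_integer_,
    n_followers = d$n_followers %||% NA_integer_,
    max_weight = d$max_weight %||% NA_real_,
    mean_weight = d$mean_weight %||% NA_real_,
    ess = d$ess %||% NA_real_
  )
}

#' Bind several estimates into a tidy results table
#'
#' @param ... `gest_estimate` objects (or lists of them).
#' @return A tibble, one row per estimate, with the standard result columns.
#' @export
estimate_table <- function(...) {
  xs <- purrr::list_flatten(list(...))
  purrr::map_dfr(xs, tidy)
}
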