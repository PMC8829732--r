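#' Validate a long-format pregnancy panel
#'
#' Checks that a long subject-time panel respects the delivery-interruption
#' structure of a pregnancy cohort and returns a validated cohort object.
#' Each subject is observed at discrete gestational times `t = 1, ..., K`
#' with covariates `W_*`, a binary exposure `A`, and a delivered-by indicator
#' `D`; a single outcome `Y` is measured at delivery for every subject,
#' whatever the delivery time. After delivery (`t > T_D`, where
#' `T_D = min{t : D(t) = 1}`) exposure and covariates are undefined and must
#' be missing.
#'
#' @param data A data frame with columns `subject_id`, `time`, `A`, `D`, `Y`
#'   and any number of covariate columns prefixed `W_`. `Y` may be repeated
#'   on every row of a subject or present only on the delivery row. Columns
#'   prefixed `C_` (or a column `C`) are accepted but ignored, with a
#'   message: censoring processes are not modelled.
#' @return An object of class `preg_cohort`: the validated long panel plus
#'   internal wide matrices used by the estimators. `as_tibble()` recovers
#'   the long panel.
#' @examples
#' panel <- tibble::tibble(
#'   subject_id = rep(1:2, each = 3), time = rep(1:3, 2),
#'   W_x = c(1, 0, NA, 0, 1, 1), A = c(0, NA, NA, 0, 0, 1),
#'   D = c(0, 1, 1, 0, 0, 1), Y = rep(c(1, 0), each = 3)
#' )
#' cohort <- validate_cohort(panel)
#' cohort$T_D
#' @export
validate_cohort <- function(data) {
  data <- tibble::as_tibble(data)
  required <- c("subject_id", "time", "A", "D", "Y")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("panel is missing required columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  cens_cols <- grep("^C($|_)", names(data), value = TRUE)
  if (length(cens_cols) > 0) {
    inform(paste0("censoring columns (", paste(cens_cols, collapse = ", "),
                  ") are accepted but ignored"))
    data <- data[setdiff(names(data), cens_cols)]
  }
  covariates <- grep("^W_", names(data), value = TRUE)
  if (length(covariates) == 0) {
    abort("panel has no covariate columns (expected at least one `W_` column)")
  }

  data <- dplyr::arrange(data, .data$subject_id, .data$time)
  subjects <- unique(data$subject_id)
  n <- length(subjects)
  times_by_subj <- split(data$time, factor(data$subject_id, levels = subjects))
  Ks <- vapply(times_by_subj, max, numeric(1))
  if (length(unique(Ks)) != 1) {
    abort("number of time points K differs across subjects")
  }
  K <- as.integer(Ks[[1]])
  ok_grid <- vapply(times_by_subj, function(tt) identical(as.integer(tt), 1:K),
                    logical(1))
  if (!all(ok_grid)) {
    abort(paste0("subject ", subjects[which(!ok_grid)[1]],
                 ": times are not the complete grid 1..K"))
  }

  to_mat <- function(col) {
    matrix(as.numeric(data[[col]]), nrow = n, ncol = K, byrow = TRUE,
           dimnames = list(NULL, NULL))
  }
  A <- to_mat("A")
  D <- to_mat("D")
  W <- lapply(setNames(covariates, covariates), to_mat)

  if (anyNA(D) || !all(D %in% c(0, 1))) {
    abort("delivery indicator D must be binary and non-missing at every time")
  }
  non_monotone <- which(apply(D, 1, function(d) any(diff(d) < 0)))
  if (length(non_monotone) > 0) {
    abort(paste0("subject ", subjects[non_monotone[1]],
                 ": delivery indicator not monotone"))
  }
  if (!all(D[, K] == 1)) {
    bad <- which(D[, K] != 1)[1]
    abort(paste0("subject ", subjects[bad],
                 ": all subjects must have delivered by time K (D(K) = 1)"))
  }
  T_D <- apply(D, 1, function(d) which(d == 1)[1])

  post <- outer(T_D, seq_len(K), function(td, t) t > td)
  if (any(!is.na(A[post]))) {
    bad <- which(rowSums(!is.na(A) & post) > 0)[1]
    abort(paste0("subject ", subjects[bad],
                 ": exposure recorded after delivery"))
  }
  # exposure unrecorded in the delivery interval itself is tolerated:
  # delivery may precede the exposure assessment, in which case the subject
  # could not have initiated and is recoded as unexposed at that time
  at_delivery <- outer(T_D, seq_len(K), function(td, t) t == td)
  na_at_delivery <- is.na(A) & at_delivery
  if (any(na_at_delivery)) {
    inform(paste0("exposure missing in the delivery interval for ",
                  sum(rowSums(na_at_delivery) > 0),
                  " subject(s); recoded as unexposed at that time"))
    A[na_at_delivery] <- 0
  }
  strictly_pre <- !post & !at_delivery
  if (any(is.na(A[strictly_pre]))) {
    bad <- which(rowSums(is.na(A) & strictly_pre) > 0)[1]
    abort(paste0("subject ", subjects[bad],
                 ": exposure missing before delivery"))
  }
  if (!all(A[!post] %in% c(0, 1))) {
    abort("exposure A must be binary")
  }
  for (wname in covariates) {
    Wm <- W[[wname]]
    if (any(!is.na(Wm[post]))) {
      bad <- which(rowSums(!is.na(Wm) & post) > 0)[1]
      abort(paste0("subject ", subjects[bad], ": covariate ", wname,
                   " recorded after delivery"))
    }
    if (any(is.na(Wm[!post]))) {
      bad <- which(rowSums(is.na(Wm) & !post) > 0)[1]
      abort(paste0("subject ", subjects[bad], ": covariate ", wname,
                   " missing before or at delivery"))
    }
  }

  y_by_subj <- split(data$Y, factor(data$subject_id, levels = subjects))
  Y <- vapply(y_by_subj, function(y) {
    y <- unique(y[!is.na(y)])
    if (length(y) == 0) return(NA_real_)
    if (length(y) > 1) return(NaN)
    y
  }, numeric(1))
  if (anyNA(Y) && any(is.na(Y) & !is.nan(Y))) {
    abort(paste0("subject ", subjects[which(is.na(Y))[1]],
                 ": outcome Y is missing (Y must be measured at delivery ",
                 "for every subject)"))
  }
  if (any(is.nan(Y))) {
    abort(paste0("subject ", subjects[which(is.nan(Y))[1]],
                 ": conflicting outcome values within subject"))
  }

  new_preg_cohort(subjects, K, W, A, D, T_D, unname(Y))
}

# internal constructor; assumes inputs already consistent
new_preg_cohort <- function(subject_id, K, W, A, D, T_D, Y) {
  # noinit_cum[i, t] = 1 iff subject i has A(l) = 0 for all l <= min(t, T_D);
  # post-delivery times contribute a factor of one
  K <- as.integer(K)
  A0 <- A
  A0[is.na(A0)] <- 0
  noinit_cum <- matrix(1, nrow(A), K)
  acc <- rep(1, nrow(A))
  for (t in seq_len(K)) {
    acc <- acc * as.numeric(A0[, t] == 0)
    noinit_cum[, t] <- acc
  }
  # first initiation time (NA if never initiated before delivery): the
  # column where the cumulative no-initiation indicator first drops to 0
  T_A <- ifelse(noinit_cum[, K] == 1, NA_integer_,
                as.integer(rowSums(noinit_cum) + 1L))
  structure(
    list(
      subject_id = subject_id,
      n = length(subject_id),
      K = as.integer(K),
      covariates = names(W),
      W = W,
      A = A,
      D = D,
      T_D = as.integer(T_D),
      T_A = as.integer(T_A),
      Y = as.numeric(Y),
      noinit_cum = noinit_cum
    ),
    class = "preg_cohort"
  )
}

#' @export
print.preg_cohort <- function(x, ...) {
  cat("<preg_cohort> ", x$n, " subjects, K = ", x$K, " time points, ",
      length(x$covariates), " covariate(s)\n", sep = "")
  cat("  delivery times: ",
      paste(sprintf("t=%d: %d", sort(unique(x$T_D)),
                    tabulate(x$T_D, x$K)[sort(unique(x$T_D))]),
            collapse = ", "), "\n", sep = "")
  cat("  initiated before delivery: ", sum(!is.na(x$T_A)), " (",
      round(100 * mean(!is.na(x$T_A)), 1), "%)\n", sep = "")
  invisible(x)
}

#' @export
as_tibble.preg_cohort <- function(x, ...) {
  out <- tibble::tibble(
    subject_id = rep(x$subject_id, each = x$K),
    time = rep(seq_len(x$K), times = x$n)
  )
  for (wname in x$covariates) out[[wname]] <- as.vector(t(x$W[[wname]]))
  out$A <- as.vector(t(x$A))
  out$D <- as.vector(t(x$D))
  out$Y <- rep(x$Y, each = x$K)
  out
}

# subject-level resample used by the bootstrap; idx indexes subjects
resample_cohort <- function(cohort, idx) {
  new_preg_cohort(
    subject_id = seq_along(idx),
    K = cohort$K,
    W = lapply(cohort$W, function(m) m[idx, , drop = FALSE]),
    A = cohort$A[idx, , drop = FALSE],
    D = cohort$D[idx, , drop = FALSE],
    T_D = cohort$T_D[idx],
    Y = cohort$Y[idx]
  )
}

check_cohort <- function(cohort) {
  if (!inherits(cohort, "preg_cohort")) {
    abort("expected a validated `preg_cohort`; run validate_cohort() first")
  }
  invisible(cohort)
}

#' Strategy-adherence indicator
#'
#' Computes `S^k(t)`, the indicator that a subject's observed exposure and
#' delivery history through time `t` is compatible with the treatment
#' strategy "initiate exposure at time `k` unless delivery has already
#' occurred". One observed history can be compatible with several strategies
#' at once: a subject untreated and undelivered through `t` follows every
#' strategy with start time after `t`, and a never-initiator who delivered
#' at `T_D` follows every strategy with `k > T_D` forever after. Strategy
#' `k = K + 1` encodes "never initiate". Post-initiation exposure values are
#' ignored: the intent-to-treat adherence logic classifies subjects by their
#' first initiation time only.
#'
#' @param cohort A `preg_cohort` from [validate_cohort()].
#' @param k Strategy start time, an integer in `1..K+1`.
#' @param t Time point, an integer in `1..K`.
#' @return Integer vector of 0/1 over subjects, in cohort order.
#' @seealso [strategy_indicators()] for the full subject-by-strategy-by-time
#'   table.
#' @export
strategy_indicator <- function(cohort, k, t) {
  check_cohort(cohort)
  K <- cohort$K
  if (t < 1 || t > K) abort("t must be in 1..K")
  if (k < 1 || k > K + 1) abort("k must be in 1..K+1")
  no_init <- cohort$noinit_cum
  m <- pmin(t, k - 1, cohort$T_D)
  pre_ok <- ifelse(m == 0, 1, no_init[cbind(seq_len(cohort$n), pmax(m, 1))])
  if (k <= t && k <= K) {
    at_k <- ifelse(k > cohort$T_D, 1, as.numeric(cohort$A[, k] == 1))
  } else {
    at_k <- 1
  }
  as.integer(pre_ok * at_k)
}

#' All strategy-adherence indicators as a tidy table
#'
#' @param cohort A `preg_cohort`.
#' @param ks Strategies to include (default all of `1..K+1`).
#' @return A tibble with columns `subject_id`, `k`, `time`, `S`.
#' @export
strategy_indicators <- function(cohort, ks = NULL) {
  check_cohort(cohort)
  ks <- ks %||% seq_len(cohort$K + 1)
  grid <- tidyr::expand_grid(k = ks, time = seq_len(cohort$K))
  purrr::pmap_dfr(grid, function(k, time) {
    S <- strategy_indicator(cohort, k, time)
    tibble::tibble(subject_id = cohort$subject_id, k = k, time = time, S = S)
  })
}

# S^k(K) for all strategies at once; n x (K+1) matrix
final_adherence_matrix <- function(cohort) {
  vapply(seq_len(cohort$K + 1),
         function(k) strategy_indicator(cohort, k, cohort$K),
         integer(cohort$n))
}
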