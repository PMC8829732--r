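# Fixtures are generated in code; nothing is read from disk.

# hand-built long panel from per-subject vectors (lists of equal-length
# vectors for A, D, W; Y one value per subject)
make_panel <- function(A, D, W, Y) {
  K <- length(A[[1]])
  purrr::map_dfr(seq_along(A), function(i) {
    tibble::tibble(subject_id = i, time = seq_len(K),
                   W_1 = W[[i]], A = A[[i]], D = D[[i]], Y = Y[i])
  })
}

# discrete two-period cohort: binary covariates, delivery possible at t = 1,
# everyone delivered by t = 2; outcome depends on covariates, an unmeasured
# cause of delivery, and delivery time
simulate_two_period <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  W1 <- rbinom(n, 1, 0.5)
  U <- rbinom(n, 1, 0.5)
  A1 <- rbinom(n, 1, plogis(-1 + 0.8 * W1))
  D1 <- rbinom(n, 1, plogis(-1.2 + 0.7 * A1 + 0.8 * U))
  W2 <- rep(NA_real_, n)
  A2 <- rep(NA_real_, n)
  und <- D1 == 0
  W2[und] <- rbinom(sum(und), 1, plogis(-0.5 + 0.9 * W1[und] + 0.6 * A1[und]))
  A2[und] <- ifelse(A1[und] == 1, 1,
                    rbinom(sum(und), 1, plogis(-0.8 + 0.7 * W2[und])))
  W2z <- ifelse(und, W2, 0)
  Y <- rbinom(n, 1, plogis(-0.7 + 0.8 * W1 + 0.6 * U + 0.5 * D1 + 0.4 * W2z))
  panel <- tibble::tibble(
    subject_id = rep(seq_len(n), each = 2),
    time = rep(1:2, n),
    W_1 = as.vector(rbind(W1, W2)),
    A = as.vector(rbind(A1, A2)),
    D = as.vector(rbind(D1, rep(1, n))),
    Y = rep(Y, each = 2)
  )
  validate_cohort(panel)
}

# brute-force g-formula on the empirical distribution of a two-period
# cohort: plain subset means and frequencies, written straight from the
# identification formula, independently of the estimation code paths
gformula_oracle_2p <- function(cohort, k) {
  stopifnot(cohort$K == 2, k %in% 1:3)
  W1 <- cohort$W$W_1[, 1]; W2 <- cohort$W$W_1[, 2]
  A1 <- cohort$A[, 1]; A2 <- cohort$A[, 2]
  D1 <- cohort$D[, 1]; Y <- cohort$Y
  a1 <- as.numeric(k == 1)
  total <- 0
  for (w1 in sort(unique(W1))) {
    pw1 <- mean(W1 == w1)
    s0 <- W1 == w1 & A1 == a1
    pd1 <- mean(D1[s0] == 1)
    m_del <- if (pd1 > 0) mean(Y[s0 & D1 == 1]) else 0
    s1 <- s0 & D1 == 0
    inner <- 0
    if (any(s1)) {
      for (w2 in sort(unique(W2[!is.na(W2)]))) {
        pw2 <- mean(W2[s1] == w2)
        if (pw2 == 0) next
        m <- switch(as.character(k),
          "1" = mean(Y[s1 & W2 == w2]),            # post-initiation A free
          "2" = mean(Y[s1 & W2 == w2 & A2 == 1]),
          "3" = mean(Y[s1 & W2 == w2 & A2 == 0])
        )
        inner <- inner + pw2 * m
      }
    }
    total <- total + pw1 * (pd1 * m_del + (1 - pd1) * inner)
  }
  total
}

# brute-force strategy-compatibility check, straight from the definition:
# loop over every constrained time instead of using cumulated indicators
oracle_strategy_indicator <- function(cohort, k, t) {
  vapply(seq_len(cohort$n), function(i) {
    td <- cohort$T_D[i]
    for (l in seq_len(t)) {
      if (l > td) next                    # post-delivery: no constraint
      a <- cohort$A[i, l]
      if (l < k && a != 0) return(0L)
      if (l == k && a != 1) return(0L)
      # l > k: post-initiation exposure ignored under ITT
    }
    1L
  }, integer(1))
}
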