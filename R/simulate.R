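#' Scenario specification for the structural simulator
#'
#' Describes one of four data-generating scenarios for a four-period
#' pregnancy cohort (`K = 4`, deliveries possible at times 2 and 3 and
#' certain by time 4) in which a baseline covariate `W(1)` and an
#' unmeasured common cause `U` of delivery time and outcome are exogenous,
#' exposure initiation depends on the current covariate, adherence is
#' perfectly sustained once initiated, delivery depends on current exposure
#' and `U`, and the binary outcome depends on `W(1)`, `W(2)`, `U`, and —
#' depending on the scenario — on delivery time and on direct exposure
#' effects:
#' \describe{
#'   \item{1}{no delivery-time effect (`beta = 1`), no direct effect: every
#'     strategy contrast is null}
#'   \item{2}{delivery time affects the outcome (`beta = 2`); effects of
#'     early initiation arise only through delivery time}
#'   \item{3}{as 2, plus a direct effect of exposure at time 2}
#'   \item{4}{as 2, plus a direct effect of exposure at time 4}
#' }
#'
#' @param scenario Integer 1–4.
#' @param n Cohort size.
#' @param coefs Named list of structural coefficients; defaults from
#'   [default_scenario_coefs()], any subset may be overridden.
#' @param delivery_effect `"per_period"` (default): each period of earlier
#'   delivery multiplies the outcome odds by `beta`; `"indicator"`: a
#'   single early-vs-full-term odds multiplier.
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(scenario, n = 1000, coefs = list(),
                          delivery_effect = c("per_period", "indicator")) {
  if (!scenario %in% 1:4) abort("scenario must be 1, 2, 3, or 4")
  delivery_effect <- match.arg(delivery_effect)
  co <- utils::modifyList(default_scenario_coefs(), coefs)
  structure(
    list(scenario = as.integer(scenario), n = as.integer(n), K = 4L,
         beta = if (scenario == 1) 1 else 2,
         direct_a2 = scenario == 3, direct_a4 = scenario == 4,
         delivery_effect = delivery_effect, coefs = co),
    class = "scenario_spec"
  )
}

#' Default structural coefficients for the simulator
#'
#' Moderate log-odds effects (log 2) on every active arrow, exogenous
#' prevalences of one half, and intercepts keeping delivery and outcome
#' prevalences well inside (0.05, 0.95) so that every discrete history cell
#' stays populated at realistic sample sizes. Treatment lowers the odds of
#' early delivery (`d_a < 0`), as for a controller medication.
#'
#' @return Named list of coefficients.
#' @export
default_scenario_coefs <- function() {
  list(
    p_w1 = 0.5, p_u = 0.5,
    w_int = qlogis(0.3), w_w = log(2), w_a = log(2),
    a_int = qlogis(0.2), a_w = log(2),
    d_int = qlogis(0.15), d_a = -log(2), d_u = log(2),
    y_int = qlogis(0.15), y_w1 = log(2), y_w2 = log(2), y_u = log(2),
    y_direct = log(2)
  )
}

# shared structural engine. uniforms: list of U(0,1) draws, reused across
# forced strategies (common random numbers). force_k = NULL draws exposure
# from the initiation model; force_k = k imposes A(t) = I(t >= k) while
# undelivered (k = K + 1 never initiates).
sim_engine <- function(spec, uniforms, force_k = NULL) {
  co <- spec$coefs
  n <- nrow(uniforms$a)
  K <- spec$K
  W1 <- as.numeric(uniforms$w1 < co$p_w1)
  U <- as.numeric(uniforms$u < co$p_u)

  W <- matrix(NA_real_, n, K); W[, 1] <- W1
  A <- matrix(NA_real_, n, K)
  D <- matrix(0, n, K)
  alive <- rep(TRUE, n)                 # undelivered entering time t
  T_D <- rep(K, n)

  for (t in seq_len(K)) {
    if (t > 1) {
      W[alive, t] <- as.numeric(
        uniforms$w[alive, t - 1] <
          plogis(co$w_int + co$w_w * W[alive, t - 1] + co$w_a * A[alive, t - 1])
      )
    }
    if (is.null(force_k)) {
      prev <- if (t == 1) rep(0, n) else A[, t - 1]
      A[alive, t] <- ifelse(
        prev[alive] == 1, 1,
        as.numeric(uniforms$a[alive, t] <
                     plogis(co$a_int + co$a_w * W[alive, t]))
      )
    } else {
      A[alive, t] <- as.numeric(t >= force_k)
    }
    if (t %in% c(2, 3)) {
      newly <- alive & (uniforms$d[, t - 1] <
                          plogis(co$d_int + co$d_a * A[, t] + co$d_u * U))
      newly[!alive] <- FALSE
      T_D[newly] <- t
      D[newly, t:K] <- 1
      alive <- alive & !newly
    }
    if (t == K) D[, K] <- 1
  }

  A2 <- A[, 2]                           # always observed (no delivery at t=1)
  A4 <- ifelse(is.na(A[, 4]), 0, A[, 4])
  early <- if (spec$delivery_effect == "per_period") K - T_D else
    as.numeric(T_D < K)
  eta <- co$y_int + co$y_w1 * W1 + co$y_w2 * W[, 2] + co$y_u * U +
    log(spec$beta) * early +
    (if (spec$direct_a2) co$y_direct * A2 else 0) +
    (if (spec$direct_a4) co$y_direct * A4 else 0)
  Y <- as.numeric(uniforms$y < plogis(eta))

  list(W1 = W1, U = U, W = W, A = A, D = D, T_D = T_D, Y = Y)
}

draw_uniforms <- function(n, K) {
  list(
    w1 = runif(n), u = runif(n),
    a = matrix(runif(n * K), n, K),
    w = matrix(runif(n * (K - 1)), n, K - 1),
    d = matrix(runif(n * 2), n, 2),
    y = runif(n)
  )
}

#' Simulate an observational cohort from a scenario
#'
#' Draws a cohort from the scenario's structural equations and returns it
#' as a validated `preg_cohort` with the delivery-interruption missingness
#' pattern applied (exposure and covariates are `NA` after delivery). The
#' unmeasured common cause `U` is not part of the cohort; it is retrievable
#' for debugging via `attr(cohort, "latent")`.
#'
#' @param spec A [scenario_spec()].
#' @param seed Optional integer seed.
#' @return A `preg_cohort` with `K = 4`.
#' @export
simulate_cohort <- function(spec, seed = NULL) {
  if (!inherits(spec, "scenario_spec")) abort("spec must be a scenario_spec")
  if (!is.null(seed)) set.seed(seed)
  sim <- sim_engine(spec, draw_uniforms(spec$n, spec$K))
  K <- spec$K
  post <- outer(sim$T_D, seq_len(K), function(td, t) t > td)
  A <- sim$A; A[post] <- NA_real_
  W2 <- sim$W; W2[post] <- NA_real_
  cohort <- new_preg_cohort(
    subject_id = seq_len(spec$n), K = K, W = list(W_1 = W2),
    A = A, D = sim$D, T_D = sim$T_D, Y = sim$Y
  )
  attr(cohort, "latent") <- tibble::tibble(U = sim$U)
  attr(cohort, "scenario") <- spec$scenario
  cohort
}

#' True counterfactual strategy means by forced-assignment simulation
#'
#' Computes the true values of `E(Y^k)` — the mean outcome had everyone
#' been assigned "initiate at `k` unless delivered" — by simulating the
#' scenario's structural equations with exposure forced to the strategy
#' (delivery still responds to the forced exposure). Common random numbers
#' are used across strategies, so contrasts are paired within simulated
#' individuals and their Monte-Carlo standard errors shrink accordingly.
#'
#' @param spec A [scenario_spec()].
#' @param ks Strategies to evaluate (default `2:5`; `5 = K + 1` is
#'   never-initiate).
#' @param n Number of simulated individuals (default `1e6`).
#' @param seed Optional integer seed.
#' @return A list of class `counterfactual_truth` with tibbles `means`
#'   (`k`, `value`, `mc_se`) and `contrasts` (`k1`, `k2`, `value`, `mc_se`,
#'   paired over adjacent `ks`), plus `n`.
#' @export
counterfactual_truth <- function(spec, ks = 2:5, n = 1e6, seed = NULL) {
  if (!inherits(spec, "scenario_spec")) abort("spec must be a scenario_spec")
  if (!is.null(seed)) set.seed(seed)
  spec$n <- as.integer(n)
  uniforms <- draw_uniforms(n, spec$K)
  Yk <- vapply(ks, function(k) sim_engine(spec, uniforms, force_k = k)$Y,
               numeric(n))
  means <- tibble::tibble(
    k = ks,
    value = colMeans(Yk),
    mc_se = apply(Yk, 2, sd) / sqrt(n)
  )
  contrasts <- if (length(ks) > 1) {
    purrr::map_dfr(seq_len(length(ks) - 1), function(i) {
      d <- Yk[, i] - Yk[, i + 1]
      tibble::tibble(k1 = ks[i], k2 = ks[i + 1],
                     value = mean(d), mc_se = sd(d) / sqrt(n))
    })
  } else {
    tibble::tibble(k1 = integer(), k2 = integer(),
                   value = numeric(), mc_se = numeric())
  }
  structure(list(means = means, contrasts = contrasts, n = n),
            class = "counterfactual_truth")
}

#' @export
print.counterfactual_truth <- function(x, ...) {
  cat("<counterfactual_truth> forced-assignment oracle, n =", x$n, "\n")
  print(x$means)
  if (nrow(x$contrasts)) print(x$contrasts)
  invisible(x)
}
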