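---
title: "Estimating gestational timing-specific exposure effects with treatment-initiation strategies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating gestational timing-specific exposure effects with treatment-initiation strategies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gestinit)
library(dplyr)
```

## The problem

Pregnancy pharmacoepidemiology asks whether starting a medication in a
particular gestational window affects a birth outcome. The obstacle is that
delivery competes with later exposure: a pregnancy that ends at 30 weeks can
never initiate a treatment scheduled for week 37. Delivery time is
simultaneously a mediator of early exposure (treatment can shift when
delivery happens, and delivery time strongly affects outcomes like
birthweight) and a contraindication for later exposure. Standard analyses
fail here in characteristic ways:

* a naive per-protocol comparison pools every early delivery into the
  "unexposed" group regardless of assignment, manufacturing a protective
  effect out of nothing (`toy_trial_expectations()` reproduces this
  arithmetic exactly);
* censoring non-full-term pregnancies estimates at best a direct effect,
  discards the component mediated by delivery time, and opens a collider
  path whenever delivery time and outcome share an unmeasured cause
  (`standard_ipw_estimate()` implements this comparator);
* a single regression with post-delivery covariates zero-filled ignores the
  delivery structure entirely (`naive_regression_estimate()`).

The estimand this package targets instead is defined through *treatment
strategies* that remain well defined for every pregnancy: "initiate
exposure at time `k` unless delivery has already occurred", for
`k = 1, ..., K` and `k = K + 1` meaning never initiate. `E(Y^k)` is the
mean outcome had everyone been assigned strategy `k` at baseline, and the
intent-to-treat (ITT) effect of exposure in window `k` is
`E(Y^k) - E(Y^(k+1))`. Because the strategy is conditional on still being
pregnant, every subject can follow it, and the contrast captures the
*total* effect — direct plus mediated through delivery time.

## Observed data and adherence

The observed data are `({W(t), A(t), D(t); t = 1..K}, Y)`: covariates,
binary exposure, a monotone delivered-by indicator with `D(K) = 1` for
everyone, and an outcome `Y` measured at delivery whatever the delivery
time (birthweight, low birth weight, neonatal survival, Apgar with
stillbirths scored 0 — the method requires an outcome defined at every
possible delivery time). After delivery (`t > T_D`) exposure and covariates
are undefined and must be missing; `validate_cohort()` enforces exactly
this shape. Exposure missing in the delivery interval itself is tolerated
and recoded to "unexposed" with a message (delivery may precede the
assessment), a convention that matters only for data assembled outside the
package.

One observed history is compatible with several strategies at once.
`strategy_indicator()` computes `S^k(t)`, the indicator that the history
through `t` is compatible with strategy `k`: untreated before `k` while
undelivered, treated at `k` if still pregnant then, and any strategy
starting after a never-initiator's delivery is followed forever. The ITT
logic classifies subjects by first initiation time only; post-initiation
exposure changes are absorbed into the ITT interpretation.

## Identification and the three estimators

Identification needs consistency, positivity (every at-risk, not-yet
initiated subject has positive probability of each future start time —
delivery itself is not a violation because post-delivery adherence is
automatic), and exchangeability with respect to the measured covariate
history, required only up to initiation and before delivery. Confounders of
*delivery time* and outcome need not be measured: the simulator's unmeasured
`U` exists precisely to demonstrate this.

**IPW.** The probability of still following strategy `k` at time `t` is the
conditional probability of remaining untreated (for `t < k`) or initiating
(at `t = k`) among undelivered, not-yet-initiated subjects, and is
identically one after delivery or after `k`. `fit_treatment_models()` fits
one initiation model per time on exactly that at-risk subset;
`cumulative_weights()` forms `w^k(t) = S^k(t) / prod P(follow)`, and
`ipw_estimate()` is the weighted outcome mean over followers (the intercept
of the weighted intercept-only regression; the weighted mean is the same
number for binary and continuous outcomes, which is why we implement it
that way). `ipw_msm()` stacks one record per subject-compatible strategy —
a subject can follow several strategies simultaneously, and stacking
realizes the summed-weight estimating equations while keeping per-strategy
bookkeeping explicit.

**G-computation.** `gcomp_estimate()` runs the iterated conditional
expectation recursion: initialize the pseudo-outcome at `Y`; at each
backward step `t = K..1`, subjects delivered by `t - 1` keep `Y` (their
outcome is known — the *delivery pass-through*), and undelivered subjects
receive a regression prediction with the exposure history set to the
strategy's values (zero before `k`, one at `k`; post-initiation exposure
never enters the conditioning set). The mean of the final iterate is the
estimate.

**TMLE.** `tmle_estimate()` targets only the *random* components of the
recursion: after each outcome regression, an intercept-only logistic
fluctuation with the current prediction's logit as offset and `w^k(t)` as
observation weights updates the predictions of undelivered subjects; known
outcomes are reintegrated untouched before the next step. The weights enter
as observation weights, which is the weighted-fluctuation variant of the
longitudinal TMLE framework (not the clever-covariate variant). The
estimator is doubly robust — consistent if either the initiation models or
the outcome regressions are — and the test suite exercises both directions
of deliberate misspecification.

## Numerical choices

* **Fluctuation solver.** The weighted score in the fluctuation intercept
  is monotone, so we solve it by bracketed root finding on `[-30, 30]`
  with tolerance `1e-12`, returning the boundary when the score does not
  change sign there (separation). After every step the weighted residual
  mean is recorded; the suite requires it below `1e-6`.
* **Probability bounding.** Initiation probabilities are clipped to
  `[prob_floor, 1 - prob_floor]`, default `0.001`, configurable, `0`
  allowed (used in the exact saturated tests). Predictions are nudged off
  exactly 0/1 by `1e-12` before taking logits.
* **Continuous outcomes.** TMLE maps the outcome affinely onto
  `[delta, 1 - delta]` (`scale_delta`, default `0.005`) so the logistic
  fluctuation machinery applies unchanged, and back-transforms the
  estimate; a linear fluctuation is available as an option. G-computation
  uses ordinary least squares steps for unbounded outcomes.
* **Learners.** Default is a main-terms logistic regression on the full
  covariate history (quasibinomial, so pseudo-outcomes in `[0, 1]` are
  handled), per time point rather than pooled. `"saturated"` gives exact
  cell frequencies for discrete histories, `"intercept"` deliberately
  ignores covariates (for misspecification experiments), and a plugin
  function hook accepts any probabilistic learner. There is no built-in
  ensemble learner; the plugin hook is the extension point.
* **Outcome-step fitting subset.** The nested expectations condition on
  having followed the strategy; the regressions are fitted on all subjects
  undelivered at `t - 1` with observed exposure history as predictors, and
  predictions are taken at the strategy-set exposure values. This
  prediction-with-intervention reading matches the iterative procedure's
  description; a `strict` mode that fits only on strategy-consistent
  subjects is provided because the conditioning statement can also be read
  as restricting the fit. Under saturated learners the two coincide.
* **Ties and degenerate inputs.** Saturated learners refuse to predict in
  history cells never observed in their fitting subset (a positivity
  violation, reported as such); a strategy with no followers through `K`
  is reported as inestimable rather than returning `NaN`; constant
  continuous outcomes cannot be scaled and error out.

## The simulator and the truth oracle

`simulate_cohort()` draws four-period cohorts (`K = 4`, deliveries possible
at times 2 and 3, certain by 4) from a fully specified structural model:
exogenous `W(1)` and an unmeasured `U` common to delivery and outcome;
initiation depending on the current covariate; perfect sustained adherence
(once exposed, always exposed — so first initiation time summarizes the
exposure path); delivery depending on current exposure and `U`; and a
binary outcome depending on `W(1)`, `W(2)`, `U`, plus scenario-specific
arrows: a delivery-time effect (odds ratio `beta = 2` per period of earlier
delivery; an indicator form is available) in scenarios 2–4, a direct effect
of `A(2)` in scenario 3 and of `A(4)` in scenario 4.

The structural coefficients are not pinned down by any published table, so
they are package defaults chosen once: exogenous prevalences of one half,
log-odds effects of `log 2` on every active arrow, intercepts placing
initiation around 20% per period, early delivery around 25–30% cumulative,
and outcome prevalence well inside `(0.05, 0.95)` so that discrete-history
cells stay populated at `n = 1000`. Treatment *lowers* the odds of early
delivery (as a controller medication would), so under scenarios 2–4 earlier
initiation is protective; all coefficients are overridable through
`scenario_spec(coefs = ...)`. Consequently the package's checks against
simulation truth are structural properties — null contrasts where no causal
path exists, unbiasedness against the oracle, the censoring comparator's
attenuation — never matches to any particular published non-null number.

`counterfactual_truth()` defines truth by brute force: it re-runs the same
structural equations with exposure forced to `I(t >= k)` while undelivered
(delivery still responds to the forced exposure) and averages the outcome,
with common random numbers across strategies so contrasts are paired within
individuals. With the delivery-time arrow active but no direct late effect,
`E(Y^4) - E(Y^5)` is *pathwise* zero — the two forced worlds are identical
draw by draw — which is the analytic anchor the acceptance checks use.

What the simulator does not emulate: censoring or loss to follow-up,
non-binary or high-dimensional covariates, imperfect adherence after
initiation, delivery at the first time point, and continuous outcomes
(tests construct those separately on top of simulated delivery times).
Passing tests therefore demonstrate correctness of the estimation machinery
under the stated structure, not robustness to everything real cohorts do.

## Experiment sizes and inference

The repeated-sampling checks use 250 repetitions of cohorts of `n = 1000`,
with truth computed at `1e6` oracle draws; bootstrap coverage uses 250
repetitions with `B = 200` resamples. Bias is declared compatible with zero
when the mean deviation from oracle truth is within three standard errors
of that mean (the across-repetition standard deviation divided by the
square root of the number of repetitions). The full-term-censoring
comparator's "estimates null effects" pattern is checked against three
across-repetition standard deviations, together with the sharper
qualitative requirements that its mean estimate is attenuated below the
true magnitude and its bias runs against the truth's sign — under our
coefficients the collider component leaves a small non-null residuum, so
exact centering on zero is a coefficient-specific accident rather than a
structural property.

Confidence intervals are percentile bootstrap over subjects (entire
trajectories, never rows), default `B = 1000` at level 0.95, with all
nuisance models refitted inside every replicate; a normal-approximation
interval is an option. Contrast intervals always come from paired replicate
differences. No influence-curve variance is implemented — the bootstrap is
the inferential tool throughout, matching how these estimators are used in
applications. Replicate failures are excluded and counted; more than 20%
failures aborts.

## A worked example

```{r example}
spec <- scenario_spec(2, n = 1500)
cohort <- simulate_cohort(spec, seed = 7)
cohort

res <- estimate_itt(cohort, method = "tmle", B = 0)
res

truth <- counterfactual_truth(spec, ks = 2:5, n = 2e5, seed = 8)
truth$contrasts
```

The contrast rows of `res` estimate the effect of initiating one period
earlier; in scenario 2 the non-null contrasts arise purely through delivery
time. With `B > 0` the same call attaches paired bootstrap intervals, and
`autoplot(res)` draws the forest plot.

## Known limitations

* Sustained-treatment (per-protocol-style) strategy estimands are out of
  scope; only the ITT start-time parameter is implemented.
* Censoring processes are not modelled; `C` columns in input files are
  accepted and ignored with a message.
* No cross-fitted or machine-learning TMLE variants; learners are
  parametric or plugin-supplied.
* The general-`K` TMLE targets once per backward step, generalizing the
  two-period worked algorithm by induction; no iterative re-targeting
  across steps is attempted.
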