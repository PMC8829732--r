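Package: gestinit
Title: Treatment-Initiation Strategy Estimators for Pregnancy Exposures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Defines and estimates intent-to-treat effects of gestational
    treatment-initiation strategies of the form "initiate exposure at time k
    unless delivery has already occurred", for pregnancy cohorts where
    delivery competes with later exposure. Provides strategy-adherence
    indicators, inverse-probability-weighted estimation, iterated
    conditional-expectation G-computation, and longitudinal targeted maximum
    likelihood estimation (TMLE) with delivery pass-through, together with
    the naive comparators these methods are designed to replace (full-term
    censored IPW, zero-filled regression, naive per-protocol contrasts), a
    structural simulator with a forced-assignment counterfactual oracle, and
    nonparametric bootstrap confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stats,
    ggplot2,
    generics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
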