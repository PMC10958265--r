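Package: needstates
Title: Multistate Survival Models for Transitions Between Met and Unmet
    Healthcare-Needs States and Death
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits three-state continuous-time Markov survival models to
    interval-censored panel data on healthcare-needs fulfilment in ageing
    cohorts, where subjects move between unmet healthcare needs, met
    healthcare needs, and death. Transition intensities follow Gompertz
    (log-linear in age) hazards with proportional covariate effects, and
    the likelihood accommodates interval censoring, right censoring, and
    exactly or approximately dated deaths. Provides maximum-likelihood
    estimation with hazard-ratio tables, covariate-profile transition
    probability prediction, and total, marginal, and state-specific
    residual life expectancies with simulation-based confidence intervals
    via piecewise-constant integration of state occupancy. Includes a
    synthetic cohort generator with known ground truth for wave-based
    observation, dropout, and death-date imputation, plus utilities to
    derive the needs state, CES-D-10 depression screening, and
    multimorbidity categories from questionnaire indicators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    deSolve,
    jsonlite,
    Matrix,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
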