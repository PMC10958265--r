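---
title: "Modelling transitions between met and unmet healthcare needs and death"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling transitions between met and unmet healthcare needs and death}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(needstates)
```

## The process and its assumptions

`needstates` models a person's healthcare-needs fulfilment in later
life as a continuous-time Markov process on three states: unmet
healthcare needs (1), met healthcare needs (2), and death (3, absorbing).
The two living states communicate — people develop unmet needs and
recover from them — and both feed mortality, giving four estimable
transitions: 1→2 (remission), 2→1 (onset), 1→3 and 2→3.

Age, not calendar time, is the process time scale: every reported
quantity (transition probabilities, life expectancies) is indexed by
age, and cohorts enter at heterogeneous baseline ages. Each transition
intensity is log-linear in age and covariates,

$$q_{rs}(a, z) = \exp\{\beta_{0,rs} + \xi_{rs}(a - 60) + \beta_{rs}^\top z\},$$

a Gompertz hazard with proportional covariate effects. The Markov
assumption — the future depends only on the current living state, age
and covariates — is what lets interval-censored panel data identify the
process: consecutive observation pairs are conditionally independent
given the earlier state.

Age is centred at 60 inside the linear predictor purely for numerical
conditioning; 60 is also the default reporting age. The same
parameterisation serves both a "covariate effect of age" reading
(hazard ratio $e^{\xi}$ per year, as in hazard-ratio tables) and the
age-varying-intensity reading used for life expectancies — they are one
model.

Covariates are sex (reference male), education in three levels
(reference low), and multimorbidity in three groups — none (reference),
physical (`P`), physical–mental (`PM`). Covariates may vary across
waves in the data; the likelihood evaluates each interval at the
interval's left endpoint (piecewise-constant covariates at observation
granularity). The `measures` utilities reconstruct these variables from
questionnaire-style indicators: the needs state from the two unmet-need
triggers (ill without outpatient care; recommended hospitalisation not
taken up), depression from the CES-D-10 at the conventional inclusive
cut-off of 10, and the multimorbidity group from a configurable
condition checklist in which screening-positive depression counts as
one mental condition.

Two readings of "two or more conditions in each category" exist for the
`PM` group, so `classify_multimorbidity()` exposes both: the default
`mixed_pair` rule (any co-occurring pair with at least one physical and
one mental condition) follows the common multimorbidity convention; the
`strict_pairs` rule demands two of each. Mental-only condition pairs
fall in `none` under either rule, since mental-only multimorbidity is
not a category of this scheme. Respondents reporting no perceived need
are coded *met*: only the two triggers define unmet needs.

## The interval-censored likelihood

Each consecutive pair of observations of a subject contributes one
factor, classified by its endpoint:

* both endpoints living: $P_{rs}(a_0, a_1)$;
* death at a known age $a_d$ (including imputed dates):
  $\sum_{s \in \{1,2\}} P_{rs}(a_0, a_d)\, q_{s3}(a_d)$ — the death
  time is exact but the living state just before death is unobserved;
* death known only to lie in the interval: $P_{r3}(a_0, a_1)$;
* alive with unknown living state (right censoring): $P_{r1} + P_{r2}$.

Whether deaths are treated as exactly dated or interval-censored is
switchable (`death_convention`), defaulting to exact — matching surveys
that collect vital status with dates, with undated deaths first passed
through `impute_death_dates()`, which draws a uniform age strictly
between the last interview and the reporting wave (the distribution of
the imputation is not dictated by anything in the data; uniform is the
neutral choice and is documented as such). Subjects observed once are
retained — they inform baseline prevalence — but contribute no pairs.
Missing covariate values are a validation error, not silently imputed:
the caller decides.

Interval probabilities use the piecewise-constant approximation: the
interval is cut into bands of width at most `h_lik` (default 1 year,
configurable), the generator is frozen at each band's *midpoint* age —
midpoint rather than left-endpoint freezing buys second-order $O(h^2)$
accuracy at no cost — and the per-band matrix exponentials are
composed. When no transition carries an age slope the process is
homogeneous and a single matrix exponential is exact and used directly.

The matrix exponential itself is closed-form: for this transition
structure the living-states block is a $2\times 2$ sub-generator whose
eigenvalues are provably real and non-positive, so $e^{tA}$ is computed
from scaled hyperbolic functions with no overflow for any parameter
values; the death column is the complement. The tests verify this
against both a general-purpose matrix exponential and direct
integration of the Kolmogorov forward equations to $10^{-8}$ per entry.

## Estimation

`fit_msm()` minimises $-2\log L$ by BFGS with finite-difference
gradients (step $10^{-5}$). Initial values are crude rates: observed
transition counts over person-years at risk in the origin state,
log-transformed, with 0.5 pseudo-counts for unobserved transitions;
age and covariate coefficients start at zero. The covariance matrix is
twice the inverse Hessian of $-2\log L$, computed at the optimum with a
larger step ($10^{-3}$) because second differences sit closer to
floating-point noise.

Rare transitions (deaths from the unmet state especially) can leave a
covariate pattern with no events, pushing a coefficient toward a
boundary and the likelihood flat along one direction. Rather than
refuse a covariance matrix, the fit floors the curvature of nearly flat
eigendirections so that their standard error is reported as 10 on the
log-hazard scale — hazard ratios effectively unbounded in both
directions — warns, and records the count (`n_flat_directions`). The
`converged` flag is honest: `FALSE` on optimiser failure or a genuinely
indefinite Hessian. Wald 95% intervals use 1.96 throughout, matching
the reporting convention of the field; `hazard_ratio_table()` intervals
are log-symmetric, so each hazard ratio is the geometric mean of its
interval endpoints.

The AIC is $-2\log L + 2k$ by definition; the full default
specification (baseline, age slope and five covariate terms on each of
four transitions) has $k = 28$.

## Life expectancies

`occupancy()` integrates the process forward from a starting age on a
grid of step `h` (default 0.5 years, distinct from the likelihood band
width) up to `max_age` (default 115 years — above the oldest ages seen
in ageing cohorts, so expectancies are effectively untruncated in
practice while remaining well-defined). State-specific residual life
expectancies $e_{rs}$ are trapezoid-rule integrals of occupancy
probabilities; marginal expectancies weight starting states by a
baseline distribution; the total is their sum and `pct_unmet` is the
unmet share of the total, all identities holding exactly by
construction.

The baseline living-state distribution at an age is estimated by
logistic regression of baseline state on age (`glm`), optionally
adjusted for covariates and evaluated at the prediction profile — a
model-based choice; an empirical age-band alternative could be
substituted via the `pi` argument, which accepts any distribution.

Confidence intervals are simulation-based: `B` (default 1000) parameter
vectors are drawn from the multivariate normal of the estimates,
every quantity recomputed per draw (vectorised across draws,
band-by-band), and 2.5/97.5 percentiles reported — percentile rather
than normal-approximation intervals, since life expectancies near
bounds are skewed. The baseline-state distribution is held at its point
estimate across draws, so its sampling error is not propagated; with
thousands of baseline observations it is negligible next to the
intensity-parameter uncertainty. Draws along floored (flat) directions
can produce extreme intensities; intensity evaluation saturates at
$10^6$/year so such draws behave as instantaneous transitions instead
of overflowing.

Multimorbidity is treated as time-fixed (baseline) in life-expectancy
estimation even when it varied in the fitted panel, because occupancy
integration requires covariates fixed along age.

## The synthetic-cohort generator

`simulate_cohort()` produces panels that emulate a three-wave ageing
cohort followed at two-year intervals from baseline ages 45–85:

* covariate marginals of 50.9% female and 45.6%/8.3% physical /
  physical–mental multimorbidity; education 67% low, with the remainder
  split 23% middle / 10% high (a typical split for such cohorts; only
  the low-education share is anchored);
* baseline unmet-needs prevalence of about 17% — consistent with the
  share of unmet-needs origin states in observed transition
  distributions — with a mild logistic age gradient;
* generating intensities from `ageing_cohort_params()`: the matrix
  logarithm of a published-style 2-year transition-probability matrix
  at the no-multimorbidity mean-covariate profile (unmet→met 0.780,
  met→unmet 0.089, unmet→death 0.011, met→death 0.013) anchors the
  age-60 baselines, shifted to the reference profile by the covariate
  log hazard ratios (onset HRs 1.85/1.45 for P/PM multimorbidity,
  remission HRs 0.58/0.64, age HRs 1.11 and 1.05 per year on the death
  intensities, and so on);
* interview-timing jitter of ±0.25 years on follow-up waves, per-wave
  dropout of 0.17 (follow-up rates near 83%), 25% of deaths with the
  date unreported, and 5% of living follow-up records with the needs
  state missing.

Trajectories are simulated by competing risks with intensities frozen
over 0.01-year internal bands; within a band, exponential waiting times
are drawn per allowed transition and the earliest applied, and a
living-state flip restarts the draw from the event time, so the scheme
is exact for frozen intensities (verified against matrix-exponential
probabilities at $10^5$ trajectories). `observe_panel()` is the
standalone wave-observation operation for externally supplied
trajectories; `simulate_cohort()` fuses generation and observation so
that censored stretches are never simulated. Time-varying
multimorbidity progression (none→P→PM between waves) is available
behind a flag, off by default.

What passing the synthetic experiments does **not** show: the generator
draws covariates independently, has no household clustering, survey
weights, or informative dropout, and its baseline states follow the
same family (logistic in age) the marginal-LE machinery assumes. Real
cohorts violate all of these; recovery of generating parameters here
demonstrates the correctness of the estimation machinery, not
robustness to misspecification.

## Numerical and testing choices

Problem sizes in the test suite are chosen to exercise the asymptotics
while keeping the default run to a few minutes: the parameter-recovery
experiment refits 25 cohorts of 2000 subjects (nominal 95% Wald
coverage is checked pooled across parameters and replicates against a
0.90 floor); Monte-Carlo comparisons use $10^5$ trajectories against
3-binomial-SE bands; convergence-order checks verify the $O(h^2)$
error decay of band halving rather than chasing absolute tolerances.
Degenerate inputs are tested explicitly: zero-length intervals
(identity), vanishing intensities (truncation-bound expectancies),
all-one-state baselines (degenerate distribution with a warning),
panels with a single observation per subject (no pairs, an error in
fitting).

Known limitations: no misclassification (hidden-Markov) layer over the
observed states; no frailty or random effects; no survey weights;
Wald-based intervals for hazard ratios (profile-likelihood intervals
would behave better for the rare unmet→death transition); and the
marginal-LE weighting inherits whatever bias the baseline-state
regression has at ages far from the data.
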