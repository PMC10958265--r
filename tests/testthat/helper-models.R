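# Shared fixtures: small parameter sets and hand-built panels.

# Time-homogeneous toy model (no age effect, no covariates) with the
# given per-year rates.
toy_params <- function(q12 = 0.4, q21 = 0.1, q13 = 0.02, q23 = 0.01) {
  msm_params(
    msm_spec(covariates = NULL, age = FALSE),
    baseline = c("1-2" = log(q12), "2-1" = log(q21),
                 "1-3" = log(q13), "2-3" = log(q23))
  )
}

# Gompertz toy model: rising death intensities, mild age trend on the
# living transitions.
gompertz_params <- function() {
  msm_params(
    msm_spec(covariates = NULL, age = TRUE),
    baseline = c("1-2" = log(0.5), "2-1" = log(0.12),
                 "1-3" = log(0.015), "2-3" = log(0.01)),
    age = c("1-2" = 0.01, "2-1" = -0.005, "1-3" = 0.07, "2-3" = 0.09)
  )
}

# One-subject panel rows with default covariates.
panel_rows <- function(subject_id, wave, age, state,
                       death_date_known = NA_integer_,
                       female = 0, edu_mid = 0, edu_high = 0,
                       multi_P = 0, multi_PM = 0) {
  tibble::tibble(
    subject_id = subject_id, wave = as.integer(wave), age = age,
    state = as.integer(state),
    death_date_known = as.integer(death_date_known),
    female = female, edu_mid = edu_mid, edu_high = edu_high,
    multi_P = multi_P, multi_PM = multi_PM
  )
}

# Generator matrix from raw rates.
raw_generator <- function(q12, q13, q21, q23) {
  Q <- matrix(0, 3, 3)
  Q[1, 2] <- q12; Q[1, 3] <- q13; Q[2, 1] <- q21; Q[2, 3] <- q23
  diag(Q) <- -rowSums(Q)
  Q
}

# Kolmogorov-forward ODE oracle for P(t) = exp(tQ), independent of the
# closed-form path under test.
ode_probability <- function(Q, t) {
  rhs <- function(time, y, parms) {
    P <- matrix(y, 3, 3)
    list(as.vector(P %*% parms))
  }
  out <- deSolve::lsoda(y = as.vector(diag(3)), times = c(0, t), func = rhs,
                        parms = Q, rtol = 1e-12, atol = 1e-12)
  matrix(out[2, -1], 3, 3)
}

# ODE oracle for age-inhomogeneous interval probabilities: integrates
# dP/da = P Q(a) exactly (up to solver tolerance), no banding.
ode_interval_probability <- function(params, z, age0, age1) {
  rhs <- function(a, y, parms) {
    P <- matrix(y, 3, 3)
    Q <- build_generator(params, a, z)
    list(as.vector(P %*% Q))
  }
  out <- deSolve::lsoda(y = as.vector(diag(3)), times = c(age0, age1),
                        func = rhs, parms = NULL, rtol = 1e-11, atol = 1e-11)
  matrix(out[2, -1], 3, 3)
}

# Reduced specification and ground truth for parameter-recovery
# experiments: Gompertz age slopes on all transitions, one covariate
# effect (physical multimorbidity raising the intensity of moving into
# unmet needs, HR 1.85).
recovery_spec <- function() {
  msm_spec(covariates = list("1-2" = NULL, "2-1" = "multi_P",
                             "1-3" = NULL, "2-3" = NULL), age = TRUE)
}

recovery_params <- function() {
  msm_params(
    recovery_spec(),
    baseline = c("1-2" = log(0.948), "2-1" = log(0.108),
                 "1-3" = log(0.00427), "2-3" = log(0.00668)),
    age = c("1-2" = log(1.01), "2-1" = 0,
            "1-3" = log(1.05), "2-3" = log(1.11)),
    beta = list("2-1" = c(multi_P = log(1.85)))
  )
}
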