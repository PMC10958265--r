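#' Specify a three-state transition-intensity model
#'
#' Declares which terms each transition intensity carries. The state
#' space and the four estimable transitions are fixed — unmet (1) and
#' met (2) healthcare needs communicate, both feed the absorbing death
#' state (3) — but the linear predictor of each transition is
#' configurable. Each intensity is log-linear:
#' \deqn{q_{rs}(a, z) = \exp\{\beta_{0,rs} + \xi_{rs}(a - a_{ref}) +
#'   \beta_{rs}'z\}}
#' so `exp(xi)` is the hazard ratio per year of age (a Gompertz age
#' effect) and `exp(beta)` the hazard ratio of a covariate.
#'
#' @param covariates Covariate terms included on every transition
#'   (subset of `female`, `edu_mid`, `edu_high`, `multi_P`, `multi_PM`),
#'   or a named list keyed by transition (`"1-2"`, `"2-1"`, `"1-3"`,
#'   `"2-3"`) for transition-specific sets.
#' @param age Include the Gompertz age slope? A single logical applied
#'   to all transitions, or a named logical vector per transition.
#' @param age_ref Centring age in years for the baseline intensity
#'   (default 60); baselines are the log intensities at this age for the
#'   reference profile.
#' @return An object of class `msm_spec`.
#' @examples
#' msm_spec()                       # full model: age + all 5 covariates
#' msm_spec(covariates = NULL)      # age-only Gompertz model
#' @export
msm_spec <- function(covariates = COVARIATE_TERMS, age = TRUE, age_ref = 60) {
  if (!is.list(covariates)) {
    covariates <- setNames(rep(list(covariates), 4), TRANSITIONS)
  }
  stopifnot(all(TRANSITIONS %in% names(covariates)))
  covariates <- lapply(covariates[TRANSITIONS], function(x) {
    x <- as.character(x %||% character())
    bad <- setdiff(x, COVARIATE_TERMS)
    if (length(bad) > 0) {
      abort(paste0("Unknown covariate term(s): ", paste(bad, collapse = ", ")))
    }
    x
  })
  if (length(age) == 1 && is.null(names(age))) {
    age <- setNames(rep(as.logical(age), 4), TRANSITIONS)
  }
  stopifnot(all(TRANSITIONS %in% names(age)))
  structure(
    list(covariates = covariates, age = age[TRANSITIONS],
         age_ref = as.numeric(age_ref)),
    class = "msm_spec"
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.msm_spec <- function(x, ...) {
  cat("Three-state needs-transition model specification\n")
  cat("  age centred at", x$age_ref, "years\n")
  for (tr in TRANSITIONS) {
    terms <- c("baseline", if (x$age[[tr]]) "age", x$covariates[[tr]])
    cat(sprintf("  %s: %s\n", tr, paste(terms, collapse = " + ")))
  }
  invisible(x)
}

#' Enumerate the free parameters of a model specification
#'
#' @param spec An [msm_spec()].
#' @return A tibble with columns `transition` and `term` in packing
#'   order; `baseline` is the log intensity at the centring age and
#'   reference profile, `age` the Gompertz slope per year.
#' @export
spec_terms <- function(spec) {
  purrr::map_dfr(TRANSITIONS, function(tr) {
    tibble::tibble(
      transition = tr,
      term = c("baseline", if (spec$age[[tr]]) "age", spec$covariates[[tr]])
    )
  })
}

#' @rdname spec_terms
#' @return `n_free_params()`: the number of free parameters (28 for the
#'   default full specification: 4 transitions x (baseline + age + 5
#'   covariates)).
#' @export
n_free_params <- function(spec) {
  nrow(spec_terms(spec))
}

#' Construct transition parameters
#'
#' Packages per-transition coefficients with their specification into an
#' `msm_params` object, the parameter container consumed by the
#' intensity, likelihood, simulation and life-expectancy functions.
#'
#' @param spec An [msm_spec()].
#' @param baseline Named numeric vector of log baseline intensities (per
#'   year, at the centring age and reference profile), one per
#'   transition `"1-2"`, `"2-1"`, `"1-3"`, `"2-3"`.
#' @param age Named numeric vector of Gompertz log-linear age slopes for
#'   the transitions whose spec includes age; missing entries default to
#'   0.
#' @param beta Named list keyed by transition of named coefficient
#'   vectors (log hazard ratios) for the covariate terms in the spec;
#'   missing entries default to 0.
#' @return An `msm_params` object: a tibble of `(transition, term,
#'   estimate)` rows with the spec attached.
#' @examples
#' msm_params(msm_spec(covariates = "multi_P"),
#'            baseline = c("1-2" = log(0.9), "2-1" = log(0.1),
#'                         "1-3" = log(0.005), "2-3" = log(0.007)),
#'            beta = list("2-1" = c(multi_P = log(1.85))))
#' @export
msm_params <- function(spec, baseline, age = NULL, beta = NULL) {
  terms <- spec_terms(spec)
  est <- numeric(nrow(terms))
  stopifnot(all(TRANSITIONS %in% names(baseline)))
  for (i in seq_len(nrow(terms))) {
    tr <- terms$transition[i]
    tm <- terms$term[i]
    est[i] <- if (tm == "baseline") {
      baseline[[tr]]
    } else if (tm == "age") {
      if (!is.null(age) && tr %in% names(age)) age[[tr]] else 0
    } else {
      (beta[[tr]] %||% numeric())[tm] %||% 0
    }
  }
  est[is.na(est)] <- 0
  new_msm_params(terms, est, spec)
}

new_msm_params <- function(terms, estimates, spec) {
  stopifnot(length(estimates) == nrow(terms), all(is.finite(estimates)))
  out <- tibble::tibble(
    transition = terms$transition, term = terms$term,
    estimate = as.numeric(estimates)
  )
  attr(out, "spec") <- spec
  class(out) <- c("msm_params", class(out))
  out
}

params_spec <- function(params) attr(params, "spec")

## Dense per-transition arrays for fast intensity evaluation:
## beta0[4], xi[4], B[4 x 5] aligned with COVARIATE_TERMS.
param_arrays <- function(params) {
  beta0 <- setNames(numeric(4), TRANSITIONS)
  xi <- setNames(numeric(4), TRANSITIONS)
  B <- matrix(0, 4, length(COVARIATE_TERMS),
              dimnames = list(TRANSITIONS, COVARIATE_TERMS))
  for (i in seq_len(nrow(params))) {
    tr <- params$transition[i]
    tm <- params$term[i]
    if (tm == "baseline") {
      beta0[tr] <- params$estimate[i]
    } else if (tm == "age") {
      xi[tr] <- params$estimate[i]
    } else {
      B[tr, tm] <- params$estimate[i]
    }
  }
  list(beta0 = beta0, xi = xi, B = B, age_ref = params_spec(params)$age_ref)
}

## Matrix logarithm of a 3x3 stochastic matrix with absorbing third
## state, via eigendecomposition (eigenvalues of such matrices with a
## valid generator are real and positive).
generator_from_p2 <- function(P, dt = 2) {
  stopifnot(all(dim(P) == c(3, 3)))
  P <- P / rowSums(P)
  e <- eigen(P)
  if (any(abs(Im(e$values)) > 1e-12) || any(Re(e$values) <= 0)) {
    abort("2-year probability matrix has no real matrix logarithm")
  }
  Q <- Re(e$vectors %*% diag(log(Re(e$values))) %*% solve(e$vectors)) / dt
  Q[3, ] <- 0
  Q[Q < 0 & row(Q) != col(Q)] <- 0
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

#' Reference generating parameters for an ageing-cohort needs model
#'
#' Builds the package's default ground-truth parameter set for synthetic
#' cohorts. Baseline intensities at age 60 are obtained by taking the
#' matrix logarithm of a 2-year transition-probability matrix typical of
#' a middle-aged and older community cohort at the mean covariate
#' profile without multimorbidity (unmet to met 0.780, met to unmet
#' 0.089, unmet to death 0.011, met to death 0.013), then shifting to
#' the reference profile (male, low education) with the covariate log
#' hazard ratios. Covariate effects are hazard ratios observed in such
#' cohorts: physical multimorbidity strongly raises the intensity of
#' moving into unmet needs (HR 1.85) and roughly halves remission (HR
#' 0.58); death intensities rise with age (HR 1.11/year from the met
#' state, 1.05/year from the unmet state).
#'
#' @param p2 Optional 3x3 2-year transition-probability matrix to
#'   calibrate baselines from; rows are states 1 (unmet), 2 (met), 3
#'   (dead).
#' @param covariate_means Covariate profile at which `p2` is taken
#'   (defaults: 50.9% female, 23% middle and 10% high education, no
#'   multimorbidity).
#' @return An `msm_params` object under the full [msm_spec()].
#' @export
ageing_cohort_params <- function(p2 = NULL, covariate_means = NULL) {
  if (is.null(p2)) {
    p2 <- rbind(c(0.209, 0.780, 0.011),
                c(0.089, 0.898, 0.013),
                c(0, 0, 1))
  }
  zbar <- covariate_means %||%
    c(female = 0.509, edu_mid = 0.23, edu_high = 0.10,
      multi_P = 0, multi_PM = 0)
  zbar <- zbar[COVARIATE_TERMS]
  Q <- generator_from_p2(p2)
  q_mean <- c("1-2" = Q[1, 2], "2-1" = Q[2, 1],
              "1-3" = Q[1, 3], "2-3" = Q[2, 3])
  beta <- list(
    "1-2" = c(female = log(1.11), edu_mid = log(1.13), edu_high = log(1.31),
              multi_P = log(0.58), multi_PM = log(0.64)),
    "2-1" = c(female = log(1.28), edu_mid = log(0.95), edu_high = log(1.20),
              multi_P = log(1.85), multi_PM = log(1.45)),
    "1-3" = c(female = log(0.42), edu_mid = log(2.12), edu_high = log(1.20),
              multi_P = log(2.81), multi_PM = log(3.99)),
    "2-3" = c(female = log(0.79), edu_mid = log(0.80), edu_high = log(0.41),
              multi_P = log(1.68), multi_PM = log(1.30))
  )
  age <- c("1-2" = log(1.01), "2-1" = 0, "1-3" = log(1.05), "2-3" = log(1.11))
  baseline <- setNames(numeric(4), TRANSITIONS)
  for (tr in TRANSITIONS) {
    baseline[tr] <- log(q_mean[[tr]]) - sum(beta[[tr]][COVARIATE_TERMS] *
                                              zbar, na.rm = TRUE)
  }
  msm_params(msm_spec(), baseline = baseline, age = age, beta = beta)
}

#' Covariate profiles for prediction
#'
#' Builds the covariate vector at which intensities, transition
#' probabilities or life expectancies are evaluated. Values may be
#' fractional (means of dummy variables) in prediction contexts, unlike
#' in data records.
#'
#' @param female,edu_mid,edu_high,multi_P,multi_PM Covariate values
#'   (0/1, or fractional means).
#' @return A named numeric profile vector.
#' @export
covariate_profile <- function(female = 0, edu_mid = 0, edu_high = 0,
                              multi_P = 0, multi_PM = 0) {
  z <- c(female = female, edu_mid = edu_mid, edu_high = edu_high,
         multi_P = multi_P, multi_PM = multi_PM)
  if (edu_mid + edu_high > 1 || multi_P + multi_PM > 1) {
    abort("education and multimorbidity dummies must each sum to at most 1")
  }
  z
}
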