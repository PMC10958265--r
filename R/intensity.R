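#' Evaluate a transition intensity
#'
#' The instantaneous rate (per year) of the transition `r-s` at a given
#' age and covariate profile under the log-linear Gompertz
#' parameterisation; see [msm_spec()] for the model form. Multiplicative
#' in covariates: `rate(z) / rate(0) = exp(beta'z)`.
#'
#' @param params An `msm_params` object.
#' @param transition One of `"1-2"`, `"2-1"`, `"1-3"`, `"2-3"`.
#' @param age Age in years (vectorised).
#' @param z Covariate profile, as from [covariate_profile()].
#' @return Intensity value(s), strictly positive.
#' @export
transition_intensity <- function(params, transition, age, z = covariate_profile()) {
  if (!transition %in% TRANSITIONS) {
    abort(paste0("Transition ", transition, " is not estimable; allowed: ",
                 paste(TRANSITIONS, collapse = ", ")))
  }
  if (any(age < 0)) abort("age must be non-negative")
  arr <- param_arrays(params)
  z <- z[COVARIATE_TERMS]
  rate <- exp(arr$beta0[[transition]] +
                arr$xi[[transition]] * (age - arr$age_ref) +
                sum(arr$B[transition, ] * z))
  if (any(!is.finite(rate))) {
    abort(paste0("Non-finite intensity for transition ", transition))
  }
  rate
}

#' Assemble the generator matrix at an age and profile
#'
#' Builds the 3x3 transition-intensity matrix Q of the three-state
#' process at a fixed age and covariate profile: off-diagonals are the
#' allowed transition intensities, disallowed transitions are exactly
#' zero, the diagonal makes rows sum to zero, and the death row is
#' identically zero (absorbing).
#'
#' @inheritParams transition_intensity
#' @return A 3x3 numeric matrix with row/column names `unmet`, `met`,
#'   `dead`.
#' @export
build_generator <- function(params, age, z = covariate_profile()) {
  Q <- matrix(0, 3, 3, dimnames = list(c("unmet", "met", "dead"),
                                       c("unmet", "met", "dead")))
  for (tr in TRANSITIONS) {
    rs <- as.integer(strsplit(tr, "-")[[1]])
    Q[rs[1], rs[2]] <- transition_intensity(params, tr, age, z)
  }
  diag(Q) <- -rowSums(Q)
  Q
}

## Intensities for many (age, covariate-row) pairs at once:
## returns an n x 4 matrix with columns in TRANSITIONS order.
##
## Rates are capped at RATE_CAP per year so that extreme parameter
## values (e.g. simulation draws along a nearly flat likelihood
## direction) saturate at an effectively instantaneous transition
## instead of overflowing to Inf.
RATE_CAP <- 1e6

intensity_rows <- function(arr, ages, Z) {
  n <- length(ages)
  out <- matrix(0, n, 4, dimnames = list(NULL, TRANSITIONS))
  da <- ages - arr$age_ref
  for (j in seq_along(TRANSITIONS)) {
    tr <- TRANSITIONS[j]
    out[, j] <- pmin(exp(arr$beta0[tr] + arr$xi[tr] * da +
                           drop(Z %*% arr$B[tr, ])), RATE_CAP)
  }
  out
}

## Vectorised matrix exponential of the living-states block.
##
## For the sub-generator A = [[-(a+b), a], [c, -(c+d)]] (a = q12,
## b = q13, c = q21, d = q23), exp(tA) = e^m [cosh(s) I +
## sinh(s)/s (tA - m I)] with m = tr(tA)/2 and s^2 = m^2 - det(tA).
## s^2 = t^2[((a+b) - (c+d))^2/4 + ac] >= 0, so both eigenvalues are
## real and the formula is exact; sinh(s)/s -> 1 handles s ~ 0.
expm_living <- function(a, b, c, d, t) {
  m <- -t * (a + b + c + d) / 2
  s2 <- (t * ((a + b) - (c + d)) / 2)^2 + t^2 * a * c
  s <- sqrt(pmax(s2, 0))
  # both eigenvalues m +/- s are <= 0, so these never overflow
  ep <- exp(m + s)
  en <- exp(m - s)
  ch <- (ep + en) / 2                                   # e^m cosh(s)
  sh_over_s <- ifelse(s > 1e-8, (ep - en) / (2 * s),    # e^m sinh(s)/s
                      exp(m) * (1 + s2 / 6))
  list(
    p11 = ch + sh_over_s * (-t * (a + b) - m),
    p12 = sh_over_s * t * a,
    p21 = sh_over_s * t * c,
    p22 = ch + sh_over_s * (-t * (c + d) - m)
  )
}

living_block_to_matrix <- function(e, i = 1) {
  P <- matrix(0, 3, 3, dimnames = list(c("unmet", "met", "dead"),
                                       c("unmet", "met", "dead")))
  P[1, 1] <- e$p11[i]; P[1, 2] <- e$p12[i]
  P[2, 1] <- e$p21[i]; P[2, 2] <- e$p22[i]
  P[1, 3] <- pmax(0, 1 - P[1, 1] - P[1, 2])
  P[2, 3] <- pmax(0, 1 - P[2, 1] - P[2, 2])
  P[3, 3] <- 1
  P
}

#' Transition probabilities of a time-homogeneous generator
#'
#' Computes `P = exp(tQ)` for a 3x3 generator with absorbing third
#' state, using the closed-form eigenstructure of the living-states
#' block (whose eigenvalues are always real for a valid generator).
#'
#' @param Q A 3x3 generator matrix, e.g. from [build_generator()].
#' @param t Interval length in years, `t >= 0`.
#' @return A 3x3 stochastic matrix; row 3 is `(0, 0, 1)`.
#' @export
expm_probability <- function(Q, t) {
  if (t < 0) abort("interval length t must be non-negative")
  stopifnot(all(dim(Q) == c(3, 3)))
  if (any(Q[row(Q) != col(Q)] < 0) || any(abs(rowSums(Q)) > 1e-9) ||
      any(Q[3, ] != 0)) {
    abort("Q is not a valid generator with absorbing third state")
  }
  e <- expm_living(Q[1, 2], Q[1, 3], Q[2, 1], Q[2, 3], t)
  living_block_to_matrix(e)
}

## Band decomposition of [age0, age1]: n bands of equal width <= h,
## with Q frozen at each band's midpoint age (second-order accurate).
age_bands <- function(age0, age1, h) {
  len <- age1 - age0
  if (len <= 0) return(list(mid = numeric(), width = numeric()))
  n <- max(1L, ceiling(len / h - 1e-9))
  w <- len / n
  list(mid = age0 + (seq_len(n) - 0.5) * w, width = rep(w, n))
}

#' Interval transition probabilities under age-varying intensities
#'
#' Transition probabilities over an age interval for the Gompertz model,
#' by piecewise-constant approximation: the interval is cut into bands
#' of width at most `h`, the generator is frozen at each band's midpoint
#' age, and the per-band matrix exponentials are composed. When no
#' transition carries an age slope the model is time-homogeneous and a
#' single matrix exponential is exact (and used).
#'
#' @inheritParams transition_intensity
#' @param age0,age1 Interval endpoints in years, `age0 <= age1`.
#' @param h Band width in years (default 1).
#' @return A 3x3 stochastic matrix of probabilities from state at
#'   `age0` to state at `age1`.
#' @export
interval_probability <- function(params, z = covariate_profile(),
                                 age0, age1, h = 1) {
  if (age1 < age0) abort("age0 must not exceed age1")
  arr <- param_arrays(params)
  if (all(arr$xi == 0)) {
    return(expm_probability(build_generator(params, age0, z), age1 - age0))
  }
  bands <- age_bands(age0, age1, h)
  if (length(bands$mid) == 0) {
    return(diag(3))
  }
  Z <- matrix(z[COVARIATE_TERMS], length(bands$mid), 5, byrow = TRUE)
  q <- intensity_rows(arr, bands$mid, Z)
  e <- expm_living(q[, "1-2"], q[, "1-3"], q[, "2-1"], q[, "2-3"],
                   bands$width)
  # sequential 2x2 product across bands
  p11 <- e$p11[1]; p12 <- e$p12[1]; p21 <- e$p21[1]; p22 <- e$p22[1]
  for (i in seq_along(bands$mid)[-1]) {
    n11 <- p11 * e$p11[i] + p12 * e$p21[i]
    n12 <- p11 * e$p12[i] + p12 * e$p22[i]
    n21 <- p21 * e$p11[i] + p22 * e$p21[i]
    n22 <- p21 * e$p12[i] + p22 * e$p22[i]
    p11 <- n11; p12 <- n12; p21 <- n21; p22 <- n22
  }
  living_block_to_matrix(list(p11 = p11, p12 = p12, p21 = p21, p22 = p22))
}
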