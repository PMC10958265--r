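## Interval-censored panel likelihood.
##
## Each consecutive observation pair contributes one factor, classified
## as:
##   "living"   — both endpoints observed in a living state: the matrix
##                element P[from, to] over the interval.
##   "death"    — endpoint dead with (possibly imputed) exact death age:
##                density sum_s P[from, s](age0, death_age) q_{s3}(death_age),
##                the penultimate living state being unknown.
##   "death_iv" — endpoint dead, death age only known to lie in the
##                interval: P[from, dead](age0, age1).
##   "censored" — endpoint alive with unknown living state: the sum of
##                the living-state probabilities from `from`.

build_pair_data <- function(panel, death_convention = c("exact", "interval")) {
  death_convention <- match.arg(death_convention)
  pairs <- panel_pairs(panel)
  if (any(!is.na(pairs$from_state) & pairs$from_state == 3L)) {
    abort("observation pair starts in the absorbing death state")
  }
  pairs <- pairs[!is.na(pairs$from_state), , drop = FALSE]
  if (nrow(pairs) == 0) abort("panel contains no likelihood pairs")

  to <- pairs$to_state
  case <- ifelse(is.na(to), "censored",
          ifelse(to != 3L, "living",
          ifelse(death_convention == "interval" |
                   is.na(pairs$death_date_known) |
                   pairs$death_date_known == 0L,
                 "death_iv", "death")))
  list(
    subject_id = pairs$subject_id,
    from = pairs$from_state,
    to = to,
    age0 = pairs$age0,
    age1 = pairs$age1,
    case = case,
    Z = as.matrix(pairs[, COVARIATE_TERMS])
  )
}

## Precompute the band decomposition and return a closure evaluating
## -2 log L at a packed parameter vector. Band structure depends only on
## the data and h, so it is built once per fit.
make_m2ll_engine <- function(panel, spec, h = 1,
                             death_convention = c("exact", "interval")) {
  pd <- build_pair_data(panel, death_convention)
  n_pairs <- length(pd$from)
  len <- pd$age1 - pd$age0
  homogeneous <- !any(unlist(spec$age))
  n_bands <- if (homogeneous) {
    rep(1L, n_pairs)
  } else {
    pmax(1L, as.integer(ceiling(len / h - 1e-9)))
  }
  width <- ifelse(n_bands > 0, len / n_bands, 0)
  band_pair <- rep(seq_len(n_pairs), n_bands)
  j_idx <- sequence(n_bands)
  mids <- pd$age0[band_pair] + (j_idx - 0.5) * width[band_pair]
  band_w <- width[band_pair]
  start <- cumsum(c(1L, n_bands))[seq_len(n_pairs)]
  Zb <- pd$Z[band_pair, , drop = FALSE]
  max_n <- max(n_bands)
  terms <- spec_terms(spec)

  is_death <- pd$case == "death"
  from1 <- pd$from == 1L

  eval_pairs <- function(est) {
    arr <- param_arrays(new_msm_params(terms, est, spec))
    q <- intensity_rows(arr, mids, Zb)
    e <- expm_living(q[, "1-2"], q[, "1-3"], q[, "2-1"], q[, "2-3"], band_w)
    p11 <- rep(1, n_pairs); p12 <- rep(0, n_pairs)
    p21 <- rep(0, n_pairs); p22 <- rep(1, n_pairs)
    for (j in seq_len(max_n)) {
      sel <- which(n_bands >= j)
      k <- start[sel] + j - 1L
      a11 <- e$p11[k]; a12 <- e$p12[k]; a21 <- e$p21[k]; a22 <- e$p22[k]
      n11 <- p11[sel] * a11 + p12[sel] * a21
      n12 <- p11[sel] * a12 + p12[sel] * a22
      n21 <- p21[sel] * a11 + p22[sel] * a21
      n22 <- p21[sel] * a12 + p22[sel] * a22
      p11[sel] <- n11; p12[sel] <- n12; p21[sel] <- n21; p22[sel] <- n22
    }
    pf1 <- ifelse(from1, p11, p21)   # P[from, 1]
    pf2 <- ifelse(from1, p12, p22)   # P[from, 2]
    lik <- numeric(n_pairs)
    liv <- pd$case == "living"
    lik[liv] <- ifelse(pd$to[liv] == 1L, pf1[liv], pf2[liv])
    cen <- pd$case == "censored"
    lik[cen] <- pf1[cen] + pf2[cen]
    div <- pd$case == "death_iv"
    lik[div] <- pmax(0, 1 - pf1[div] - pf2[div])
    if (any(is_death)) {
      qd <- intensity_rows(arr, pd$age1[is_death],
                           pd$Z[is_death, , drop = FALSE])
      lik[is_death] <- pf1[is_death] * qd[, "1-3"] +
        pf2[is_death] * qd[, "2-3"]
    }
    lik
  }

  m2ll <- function(est) {
    lik <- eval_pairs(est)
    if (any(lik <= 0 | !is.finite(lik))) {
      return(Inf)
    }
    -2 * sum(log(lik))
  }
  list(m2ll = m2ll, eval_pairs = eval_pairs, pair_data = pd,
       n_pairs = n_pairs,
       n_subjects = length(unique(panel$subject_id)))
}

#' Log-likelihood contribution of one observation pair
#'
#' The log probability (or, for exactly dated deaths, log density)
#' contributed by a pair of consecutive observations of one subject
#' under the interval-censored panel likelihood. The pair is classified
#' from its endpoint: both endpoints living, death at a known age
#' (summing over the unknown penultimate living state), death within the
#' interval, or alive with unknown state (`to_state = NA`).
#'
#' @param params An `msm_params` object.
#' @param from_state Living state (1 or 2) at the start of the interval.
#' @param to_state State at the end: 1, 2, 3, or `NA` for
#'   alive-with-unknown-state.
#' @param age0,age1 Ages in years at the two observations (for an
#'   exactly dated death, `age1` is the death age).
#' @param z Covariate profile over the interval (left-endpoint values).
#' @param death_date_known For `to_state = 3`: is `age1` the death age
#'   (1) or the reporting-wave age with death somewhere in the interval
#'   (0)?
#' @param h Band width in years for the piecewise-constant
#'   approximation.
#' @param death_convention `"exact"` (default) or `"interval"`; the
#'   latter treats all deaths as interval-censored.
#' @return The log-likelihood contribution (`<= 0` for probability
#'   cases; exactly dated deaths contribute a log density which may
#'   exceed 0).
#' @export
pair_log_likelihood <- function(params, from_state, to_state, age0, age1,
                                z = covariate_profile(),
                                death_date_known = 1L, h = 1,
                                death_convention = "exact") {
  if (!from_state %in% c(1L, 2L)) {
    abort("from_state must be a living state (1 or 2)")
  }
  if (age1 < age0) abort("age0 must not exceed age1")
  panel <- tibble::tibble(
    subject_id = "pair", wave = c(0L, 1L), age = c(age0, age1),
    state = as.integer(c(from_state, to_state)),
    death_date_known = c(NA_integer_, as.integer(death_date_known))
  )
  for (v in COVARIATE_TERMS) panel[[v]] <- z[[v]]
  if (age1 == age0) {
    # zero-length interval: P is the identity
    if (!is.na(to_state) && to_state == from_state) return(0)
  }
  eng <- make_m2ll_engine(panel, params_spec(params), h, death_convention)
  log(eng$eval_pairs(params$estimate))
}

#' Total -2 log-likelihood of a panel
#'
#' Sums the pairwise contributions over all subjects and consecutive
#' observation pairs (by the Markov property, pairs are conditionally
#' independent given the earlier state) and returns -2 times the total,
#' the scale on which model fit and AIC are reported.
#'
#' @param panel A valid panel tibble.
#' @param params An `msm_params` object.
#' @inheritParams pair_log_likelihood
#' @return A scalar; `Inf` (with a warning identifying the offending
#'   subject) if any pair has zero likelihood.
#' @export
total_neg2_loglik <- function(panel, params, h = 1,
                              death_convention = "exact") {
  eng <- make_m2ll_engine(panel, params_spec(params), h, death_convention)
  lik <- eng$eval_pairs(params$estimate)
  bad <- which(lik <= 0 | !is.finite(lik))
  if (length(bad) > 0) {
    warn(paste0("Zero-likelihood pair(s) for subject(s): ",
                paste(unique(eng$pair_data$subject_id[bad]), collapse = ", ")))
    return(Inf)
  }
  -2 * sum(log(lik))
}
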