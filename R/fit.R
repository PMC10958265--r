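#' Fit the three-state needs-transition model by maximum likelihood
#'
#' Maximises the interval-censored panel likelihood over all transition
#' parameters simultaneously (quasi-Newton BFGS on -2 log L), with
#' crude-rate initial values: each baseline starts at the log of the
#' observed transition count divided by person-years at risk in the
#' origin state, and age and covariate coefficients start at zero. The
#' covariance matrix is the inverse of the numerically differentiated
#' observed information at the optimum.
#'
#' @param panel A valid panel tibble (see [read_panel()]).
#' @param spec An [msm_spec()]; defaults to the full model (Gompertz age
#'   plus all five covariates on each transition).
#' @param h Band width in years for the piecewise-constant likelihood
#'   approximation (default 1).
#' @param death_convention `"exact"` (default) or `"interval"`.
#' @param init Optional numeric vector of starting values in
#'   [spec_terms()] order; overrides crude-rate initialisation.
#' @param control Passed to [stats::optim()] (method `"BFGS"`).
#' @return An object of class `msm_fit` with components `params`
#'   (an `msm_params` tibble of estimates), `vcov`, `minus2loglik`, `k`,
#'   `aic` (`= minus2loglik + 2k`), `converged`, `gradient_norm`,
#'   `n_subjects`, `n_pairs`.
#' @seealso [hazard_ratio_table()], [predict_transition_probabilities()],
#'   [life_expectancies()]
#' @export
fit_msm <- function(panel, spec = msm_spec(), h = 1,
                    death_convention = "exact", init = NULL,
                    control = list()) {
  eng <- make_m2ll_engine(panel, spec, h, death_convention)
  terms <- spec_terms(spec)
  k <- nrow(terms)
  if (is.null(init)) {
    init <- crude_init(panel, spec)
  }
  stopifnot(length(init) == k)
  if (!is.finite(eng$m2ll(init))) {
    abort(paste0(
      "Likelihood is non-finite at the starting values; supply `init` ",
      "near plausible log intensities (crude-rate initialisation failed)"
    ))
  }
  control <- utils::modifyList(
    list(maxit = 500L, reltol = 1e-12, ndeps = rep(1e-5, k)), control
  )
  opt <- stats::optim(init, eng$m2ll, method = "BFGS", control = control)
  est <- opt$par
  grad <- num_gradient(eng$m2ll, est)
  # second differences need a larger step than the gradient to stay
  # above floating-point noise on a likelihood of this magnitude
  H <- stats::optimHess(est, eng$m2ll, control = list(ndeps = rep(1e-3, k)))
  H <- (H + t(H)) / 2
  vcov <- NULL
  n_flat <- 0L
  hess_ok <- FALSE
  ev <- tryCatch(eigen(H, symmetric = TRUE), error = function(e) NULL)
  if (!is.null(ev) && all(is.finite(ev$values)) && max(ev$values) > 0) {
    # eigenvalues within finite-difference noise of zero count as flat,
    # not indefinite
    hess_ok <- all(ev$values > -1e-8 * max(ev$values))
    # -2 log L curvature is twice the observed information; nearly flat
    # directions (boundary estimates, e.g. a transition with no events
    # for a covariate pattern) get their variance floored at 100 on the
    # log-hazard scale — a standard error of 10, i.e. effectively
    # unbounded hazard ratios
    n_flat <- sum(ev$values < 2 / 100)
    lam <- pmax(ev$values, 2 / 100)
    vcov <- 2 * ev$vectors %*% (t(ev$vectors) / lam)
    if (n_flat > 0) {
      warn(paste0(n_flat, " direction(s) of the likelihood are nearly ",
                  "flat at the optimum; their standard errors are ",
                  "reported as 10 on the log-hazard scale"))
    }
  } else {
    warn("Hessian unusable; no covariance matrix returned")
  }
  m2ll <- opt$value
  structure(
    list(
      params = new_msm_params(terms, est, spec),
      spec = spec,
      vcov = vcov,
      minus2loglik = m2ll,
      k = k,
      aic = m2ll + 2 * k,
      converged = opt$convergence == 0 && hess_ok,
      n_flat_directions = n_flat,
      gradient_norm = sqrt(sum(grad^2)),
      n_subjects = eng$n_subjects,
      n_pairs = eng$n_pairs,
      h = h,
      death_convention = death_convention,
      optim = opt[c("convergence", "counts", "message")]
    ),
    class = "msm_fit"
  )
}

## Crude-rate starting values: observed transition counts over
## person-years at risk in the origin state, log-transformed; 0.5 counts
## for unobserved transitions so the log is finite.
crude_init <- function(panel, spec) {
  pd <- build_pair_data(panel)
  counts <- transition_count_table(panel)
  # interval-censored deaths are absent from the count table's column 3
  counts[1, 3] <- counts[1, 3] + sum(pd$case == "death_iv" & pd$from == 1L)
  counts[2, 3] <- counts[2, 3] + sum(pd$case == "death_iv" & pd$from == 2L)
  py <- c(sum(pd$age1[pd$from == 1L] - pd$age0[pd$from == 1L]),
          sum(pd$age1[pd$from == 2L] - pd$age0[pd$from == 2L]))
  py <- pmax(py, 1e-8)
  crude <- c("1-2" = max(counts[1, 2], 0.5) / py[1],
             "2-1" = max(counts[2, 1], 0.5) / py[2],
             "1-3" = max(counts[1, 3], 0.5) / py[1],
             "2-3" = max(counts[2, 3], 0.5) / py[2])
  terms <- spec_terms(spec)
  init <- numeric(nrow(terms))
  for (i in seq_len(nrow(terms))) {
    if (terms$term[i] == "baseline") init[i] <- log(crude[[terms$transition[i]]])
  }
  init
}

num_gradient <- function(f, x, eps = 1e-6) {
  vapply(seq_along(x), function(i) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + eps
    xm[i] <- xm[i] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, numeric(1))
}

#' @export
print.msm_fit <- function(x, ...) {
  cat("Three-state needs-transition model fit\n")
  cat(sprintf("  subjects: %d, transition pairs: %d\n",
              x$n_subjects, x$n_pairs))
  cat(sprintf("  -2 log-likelihood: %.2f, AIC: %.2f (k = %d)\n",
              x$minus2loglik, x$aic, x$k))
  cat(sprintf("  converged: %s (|gradient| = %.2e)\n",
              x$converged, x$gradient_norm))
  if (x$n_flat_directions > 0) {
    cat(sprintf("  note: %d nearly flat likelihood direction(s); affected\n",
                x$n_flat_directions))
    cat("  standard errors are reported as 10 on the log-hazard scale\n")
  }
  invisible(x)
}

#' Tidy a fitted needs-transition model
#'
#' @param x An `msm_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per free parameter: `transition`,
#'   `term`, `estimate` (log scale), `std.error`, `conf.low`,
#'   `conf.high` (Wald, log scale).
#' @method tidy msm_fit
#' @export
tidy.msm_fit <- function(x, ...) {
  out <- tibble::as_tibble(x$params)
  se <- if (is.null(x$vcov)) NA_real_ else sqrt(pmax(diag(x$vcov), 0))
  out$std.error <- se
  out$conf.low <- out$estimate - 1.96 * se
  out$conf.high <- out$estimate + 1.96 * se
  out
}

#' Model-level summary of a fitted needs-transition model
#'
#' @inheritParams tidy.msm_fit
#' @return A one-row tibble: `minus2loglik`, `AIC`, `k`, `n_subjects`,
#'   `n_pairs`, `converged`.
#' @method glance msm_fit
#' @export
glance.msm_fit <- function(x, ...) {
  tibble::tibble(
    minus2loglik = x$minus2loglik, AIC = x$aic, k = x$k,
    n_subjects = x$n_subjects, n_pairs = x$n_pairs, converged = x$converged
  )
}

#' Hazard-ratio table of a fitted model
#'
#' Exponentiates the age and covariate coefficients into hazard ratios
#' with log-symmetric 95% Wald intervals, the conventional reporting
#' scale for covariate effects on transition intensities. Baseline
#' rows (log intensities, not ratios) are omitted.
#'
#' @param fit An `msm_fit` with a covariance matrix.
#' @return A tibble with columns `transition`, `term`, `hr`, `ci_low`,
#'   `ci_high`, `se_log`. The age row is the hazard ratio per year of
#'   age.
#' @export
hazard_ratio_table <- function(fit) {
  if (is.null(fit$vcov)) {
    abort("fit has no covariance matrix; cannot form Wald intervals")
  }
  td <- tidy.msm_fit(fit)
  td <- td[td$term != "baseline", , drop = FALSE]
  tibble::tibble(
    transition = td$transition,
    term = td$term,
    hr = exp(td$estimate),
    ci_low = exp(td$conf.low),
    ci_high = exp(td$conf.high),
    se_log = td$std.error
  )
}

#' Predict interval transition probabilities at a covariate profile
#'
#' Transition probabilities over a horizon from a given age at an
#' arbitrary (possibly fractional, dummy-mean) covariate profile, with
#' optional simulation-based confidence intervals obtained by drawing
#' parameter vectors from the asymptotic normal of the estimates and
#' recomputing the probabilities per draw.
#'
#' @param fit An `msm_fit`.
#' @param z Covariate profile, e.g. [covariate_profile()]; fractional
#'   values (means of dummies) are allowed here.
#' @param age Starting age in years.
#' @param horizon Interval length in years (default 2).
#' @param h Band width for the piecewise-constant approximation;
#'   defaults to the fit's.
#' @param ci Add percentile confidence intervals?
#' @param B Number of parameter draws for the intervals.
#' @param seed Optional seed for the draws.
#' @return A tibble with columns `from`, `to`, `estimate` and, if
#'   requested, `conf.low`, `conf.high`; rows cover the two living
#'   origin states and all three destinations (each origin's
#'   probabilities sum to 1).
#' @export
predict_transition_probabilities <- function(fit, z = covariate_profile(),
                                             age = 60, horizon = 2,
                                             h = fit$h, ci = FALSE,
                                             B = 1000, seed = NULL) {
  if (horizon < 0) abort("horizon must be non-negative")
  P <- interval_probability(fit$params, z, age, age + horizon, h)
  states <- c("unmet", "met", "dead")
  out <- tidyr::expand_grid(from = states[1:2], to = states)
  out$estimate <- as.vector(t(P[1:2, ]))
  if (ci) {
    draws <- draw_params(fit, B, seed)
    sims <- vapply(seq_len(B), function(b) {
      Pb <- interval_probability(draws[[b]], z, age, age + horizon, h)
      as.vector(t(Pb[1:2, ]))
    }, numeric(6))
    out$conf.low <- apply(sims, 1, quantile, probs = 0.025)
    out$conf.high <- apply(sims, 1, quantile, probs = 0.975)
  }
  out
}

## B parameter draws from MVN(estimates, vcov) as msm_params objects.
draw_params <- function(fit, B, seed = NULL) {
  if (is.null(fit$vcov)) {
    abort("fit has no covariance matrix; cannot simulate parameter draws")
  }
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  m <- MASS::mvrnorm(B, mu = fit$params$estimate, Sigma = fit$vcov)
  if (B == 1) m <- matrix(m, nrow = 1)
  terms <- spec_terms(fit$spec)
  lapply(seq_len(B), function(b) new_msm_params(terms, m[b, ], fit$spec))
}
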