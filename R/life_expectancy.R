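#' State-occupancy probabilities along an age grid
#'
#' Forward-integrates the three-state process from a starting age to a
#' maximum age by piecewise-constant approximation: the generator is
#' frozen at each band's midpoint age and the per-band matrix
#' exponentials are composed cumulatively. Row `r` of the result at grid
#' age `a` is the distribution over states at `a` for a subject in
#' living state `r` at the starting age.
#'
#' @param object An `msm_fit` or `msm_params` object.
#' @param z Covariate profile (fractional dummy means allowed).
#' @param start_age Starting age in years.
#' @param h Grid step in years (default 0.5).
#' @param max_age Upper truncation age in years (default 115, beyond the
#'   oldest ages observed in ageing cohorts).
#' @return A tibble of class `occupancy_grid`: one row per grid age with
#'   columns `age` and `p<r><s>` for r in 1:2, s in 1:3 (occupancy
#'   probability of state s at `age` given living state r at
#'   `start_age`). Each row's triple per starting state sums to 1.
#' @export
occupancy <- function(object, z = covariate_profile(), start_age = 60,
                      h = 0.5, max_age = 115) {
  params <- as_msm_params(object)
  if (start_age >= max_age) abort("start_age must be below max_age")
  if (h <= 0) abort("grid step h must be positive")
  arr <- param_arrays(params)
  n <- ceiling((max_age - start_age) / h - 1e-9)
  edges <- c(start_age + (0:(n - 1)) * h, max_age)
  widths <- diff(edges)
  mids <- edges[-length(edges)] + widths / 2
  Z <- matrix(z[COVARIATE_TERMS], length(mids), 5, byrow = TRUE)
  q <- intensity_rows(arr, mids, Z)
  e <- expm_living(q[, "1-2"], q[, "1-3"], q[, "2-1"], q[, "2-3"], widths)
  m <- length(mids)
  p11 <- numeric(m + 1); p12 <- numeric(m + 1)
  p21 <- numeric(m + 1); p22 <- numeric(m + 1)
  p11[1] <- 1; p22[1] <- 1
  for (i in seq_len(m)) {
    p11[i + 1] <- p11[i] * e$p11[i] + p12[i] * e$p21[i]
    p12[i + 1] <- p11[i] * e$p12[i] + p12[i] * e$p22[i]
    p21[i + 1] <- p21[i] * e$p11[i] + p22[i] * e$p21[i]
    p22[i + 1] <- p21[i] * e$p12[i] + p22[i] * e$p22[i]
  }
  out <- tibble::tibble(
    age = edges,
    p11 = p11, p12 = p12, p13 = pmax(0, 1 - p11 - p12),
    p21 = p21, p22 = p22, p23 = pmax(0, 1 - p21 - p22)
  )
  attr(out, "start_age") <- start_age
  attr(out, "max_age") <- max_age
  attr(out, "profile") <- z
  class(out) <- c("occupancy_grid", class(out))
  out
}

as_msm_params <- function(object) {
  if (inherits(object, "msm_fit")) return(object$params)
  if (inherits(object, "msm_params")) return(object)
  abort("expected an `msm_fit` or `msm_params` object")
}

#' State-specific residual life expectancy from an occupancy grid
#'
#' Expected years spent in living state `state` between the grid's
#' starting age and its maximum age for a subject in living state `from`
#' at the starting age, by trapezoid-rule integration of the occupancy
#' probabilities.
#'
#' @param grid An [occupancy()] grid.
#' @param from Starting living state, 1 (unmet) or 2 (met).
#' @param state Living state whose residence time is integrated.
#' @return Years (non-negative scalar).
#' @export
state_specific_le <- function(grid, from, state) {
  stopifnot(from %in% 1:2, state %in% 1:2)
  p <- grid[[paste0("p", from, state)]]
  trapezoid(grid$age, p)
}

trapezoid <- function(x, y) {
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

#' Baseline living-state distribution at an age
#'
#' Estimates the probability of being in the unmet-needs state among the
#' living at a given age, from the baseline (first) observation of each
#' subject, by logistic regression of state on age — the weighting
#' distribution used for marginal life expectancies. Covariates can
#' optionally enter the regression, in which case the distribution is
#' evaluated at the supplied profile.
#'
#' @param panel A valid panel tibble.
#' @param age Age in years at which to evaluate the distribution.
#' @param z Covariate profile, used only when `include_covariates` is
#'   `TRUE`.
#' @param include_covariates Adjust the baseline-state regression for
#'   the model covariates?
#' @return Named numeric vector `c(pi_1, pi_2)` summing to 1.
#' @export
initial_state_distribution <- function(panel, age, z = covariate_profile(),
                                       include_covariates = FALSE) {
  base <- panel[!duplicated(panel$subject_id), , drop = FALSE]
  base <- base[!is.na(base$state) & base$state %in% c(1L, 2L), , drop = FALSE]
  if (nrow(base) == 0) abort("panel has no baseline living-state records")
  y <- as.integer(base$state == 1L)
  if (length(unique(y)) == 1) {
    warn("all baseline subjects in one living state; degenerate distribution")
    pi1 <- as.numeric(y[1] == 1L)
    return(c(pi_1 = pi1, pi_2 = 1 - pi1))
  }
  if (include_covariates) {
    df <- data.frame(y = y, age = base$age,
                     base[, COVARIATE_TERMS, drop = FALSE])
    fit <- glm(y ~ ., family = binomial(), data = df)
    newdata <- data.frame(age = age, as.list(z[COVARIATE_TERMS]))
  } else {
    fit <- glm(y ~ age, family = binomial(), data = data.frame(y = y,
                                                               age = base$age))
    newdata <- data.frame(age = age)
  }
  pi1 <- as.numeric(stats::predict(fit, newdata = newdata, type = "response"))
  c(pi_1 = pi1, pi_2 = 1 - pi1)
}

#' Total, marginal and state-specific residual life expectancies
#'
#' Composes the occupancy integration with the baseline living-state
#' distribution into the full life-expectancy set at an age and
#' covariate profile: state-specific expectancies `e_rs` (years in
#' living state s given living state r at the starting age), marginal
#' expectancies `marginal_s = pi_1 e_1s + pi_2 e_2s`, total life
#' expectancy `total = marginal_unmet + marginal_met`, and the
#' percentage of total life expectancy spent with unmet needs
#' `pct_unmet = 100 marginal_unmet / total`. The identities hold exactly
#' by construction.
#'
#' @inheritParams occupancy
#' @param panel Panel used to estimate the baseline state distribution;
#'   ignored when `pi` is given.
#' @param pi Optional initial living-state distribution `c(pi_1, pi_2)`;
#'   overrides the panel-based estimate.
#' @param include_covariates Passed to [initial_state_distribution()].
#' @return A one-row tibble of class `le_set`: `start_age`, `pi_1`,
#'   `e_11`, `e_12`, `e_21`, `e_22`, `marginal_unmet`, `marginal_met`,
#'   `total`, `pct_unmet`.
#' @export
life_expectancies <- function(object, panel = NULL, z = covariate_profile(),
                              start_age = 60, h = 0.5, max_age = 115,
                              pi = NULL, include_covariates = FALSE) {
  if (is.null(pi)) {
    if (is.null(panel)) {
      abort("supply either `panel` (to estimate pi) or `pi` directly")
    }
    pi <- initial_state_distribution(panel, start_age, z, include_covariates)
  }
  stopifnot(length(pi) == 2, abs(sum(pi) - 1) < 1e-8, all(pi >= 0))
  grid <- occupancy(object, z, start_age, h, max_age)
  e11 <- state_specific_le(grid, 1, 1)
  e12 <- state_specific_le(grid, 1, 2)
  e21 <- state_specific_le(grid, 2, 1)
  e22 <- state_specific_le(grid, 2, 2)
  marg1 <- pi[[1]] * e11 + pi[[2]] * e21
  marg2 <- pi[[1]] * e12 + pi[[2]] * e22
  total <- marg1 + marg2
  out <- tibble::tibble(
    start_age = start_age, pi_1 = pi[[1]],
    e_11 = e11, e_12 = e12, e_21 = e21, e_22 = e22,
    marginal_unmet = marg1, marginal_met = marg2,
    total = total, pct_unmet = pct_unmet(marg1, total)
  )
  attr(out, "profile") <- z
  class(out) <- c("le_set", class(out))
  out
}

#' Percentage of total life expectancy spent with unmet needs
#'
#' @param marginal_unmet Marginal life expectancy with unmet needs
#'   (years).
#' @param total Total life expectancy (years).
#' @return `100 * marginal_unmet / total`.
#' @export
pct_unmet <- function(marginal_unmet, total) {
  100 * marginal_unmet / total
}

## Fast life-expectancy evaluation for a matrix of parameter vectors
## (rows), vectorised across draws band-by-band. Returns a B x 4 matrix
## of e_11, e_12, e_21, e_22.
le_for_draws <- function(est_matrix, spec, z, start_age, h, max_age) {
  terms <- spec_terms(spec)
  B <- nrow(est_matrix)
  z <- z[COVARIATE_TERMS]
  # per-transition: base linear predictor at the profile, and age slope
  base <- matrix(0, B, 4, dimnames = list(NULL, TRANSITIONS))
  xi <- matrix(0, B, 4, dimnames = list(NULL, TRANSITIONS))
  for (i in seq_len(nrow(terms))) {
    tr <- terms$transition[i]
    tm <- terms$term[i]
    if (tm == "baseline") {
      base[, tr] <- base[, tr] + est_matrix[, i]
    } else if (tm == "age") {
      xi[, tr] <- est_matrix[, i]
    } else {
      base[, tr] <- base[, tr] + est_matrix[, i] * z[[tm]]
    }
  }
  n <- ceiling((max_age - start_age) / h - 1e-9)
  edges <- c(start_age + (0:(n - 1)) * h, max_age)
  widths <- diff(edges)
  mids <- edges[-length(edges)] + widths / 2
  p11 <- rep(1, B); p12 <- rep(0, B); p21 <- rep(0, B); p22 <- rep(1, B)
  e <- matrix(0, B, 4, dimnames = list(NULL, c("e_11", "e_12", "e_21", "e_22")))
  for (i in seq_along(mids)) {
    da <- mids[i] - spec$age_ref
    q12 <- pmin(exp(base[, "1-2"] + xi[, "1-2"] * da), RATE_CAP)
    q21 <- pmin(exp(base[, "2-1"] + xi[, "2-1"] * da), RATE_CAP)
    q13 <- pmin(exp(base[, "1-3"] + xi[, "1-3"] * da), RATE_CAP)
    q23 <- pmin(exp(base[, "2-3"] + xi[, "2-3"] * da), RATE_CAP)
    eb <- expm_living(q12, q13, q21, q23, widths[i])
    n11 <- p11 * eb$p11 + p12 * eb$p21
    n12 <- p11 * eb$p12 + p12 * eb$p22
    n21 <- p21 * eb$p11 + p22 * eb$p21
    n22 <- p21 * eb$p12 + p22 * eb$p22
    w <- widths[i] / 2
    e[, "e_11"] <- e[, "e_11"] + w * (p11 + n11)
    e[, "e_12"] <- e[, "e_12"] + w * (p12 + n12)
    e[, "e_21"] <- e[, "e_21"] + w * (p21 + n21)
    e[, "e_22"] <- e[, "e_22"] + w * (p22 + n22)
    p11 <- n11; p12 <- n12; p21 <- n21; p22 <- n22
  }
  e
}

#' Simulation-based confidence intervals for life expectancies
#'
#' Draws parameter vectors from the multivariate normal distribution of
#' the maximum-likelihood estimates, recomputes every life-expectancy
#' quantity per draw, and reports 2.5/97.5 percentile intervals — the
#' simulation approach conventional for health-expectancy estimates,
#' reproducible under a fixed seed. The initial living-state
#' distribution is held at its point estimate across draws.
#'
#' @inheritParams life_expectancies
#' @param object An `msm_fit` with a covariance matrix.
#' @param B Number of parameter draws (default 1000).
#' @param seed Optional integer seed for the draws.
#' @return A tibble of class `le_ci`: one row per quantity (`e_11`,
#'   `e_12`, `e_21`, `e_22`, `marginal_unmet`, `marginal_met`, `total`,
#'   `pct_unmet`) with `estimate`, `conf.low`, `conf.high`.
#' @export
le_confidence_intervals <- function(object, panel = NULL,
                                    z = covariate_profile(), start_age = 60,
                                    B = 1000, seed = NULL, h = 0.5,
                                    max_age = 115, pi = NULL,
                                    include_covariates = FALSE) {
  if (!inherits(object, "msm_fit") || is.null(object$vcov)) {
    abort("need an `msm_fit` with a covariance matrix")
  }
  if (B < 2) abort("B must be at least 2")
  if (is.null(pi)) {
    if (is.null(panel)) {
      abort("supply either `panel` (to estimate pi) or `pi` directly")
    }
    pi <- initial_state_distribution(panel, start_age, z, include_covariates)
  }
  point <- life_expectancies(object, z = z, start_age = start_age, h = h,
                             max_age = max_age, pi = pi)
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  sig <- (object$vcov + t(object$vcov)) / 2
  draws <- MASS::mvrnorm(B, mu = object$params$estimate, Sigma = sig)
  e <- le_for_draws(draws, object$spec, z, start_age, h, max_age)
  marg1 <- pi[[1]] * e[, "e_11"] + pi[[2]] * e[, "e_21"]
  marg2 <- pi[[1]] * e[, "e_12"] + pi[[2]] * e[, "e_22"]
  total <- marg1 + marg2
  qmat <- cbind(e, marginal_unmet = marg1, marginal_met = marg2,
                total = total, pct_unmet = pct_unmet(marg1, total))
  est <- c(point$e_11, point$e_12, point$e_21, point$e_22,
           point$marginal_unmet, point$marginal_met, point$total,
           point$pct_unmet)
  out <- tibble::tibble(
    quantity = colnames(qmat),
    estimate = est,
    conf.low = unname(apply(qmat, 2, quantile, probs = 0.025)),
    conf.high = unname(apply(qmat, 2, quantile, probs = 0.975))
  )
  attr(out, "B") <- B
  attr(out, "start_age") <- start_age
  attr(out, "profile") <- z
  class(out) <- c("le_ci", class(out))
  out
}

#' Plot life-expectancy estimates with confidence intervals
#'
#' @param object A `le_ci` tibble from [le_confidence_intervals()].
#' @param ... Unused.
#' @return A ggplot: point estimates with 95% interval bars per
#'   quantity.
#' @method autoplot le_ci
#' @export
autoplot.le_ci <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$quantity,
                                       y = .data$estimate)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$conf.low,
                                          ymax = .data$conf.high)) +
    ggplot2::labs(x = NULL, y = "years (pct_unmet: %)",
                  title = paste0("Residual life expectancies at age ",
                                 attr(object, "start_age"))) +
    ggplot2::theme_minimal()
}

#' Marginal life expectancies across starting ages
#'
#' Computes marginal unmet- and met-needs life expectancies on a grid of
#' starting ages at a fixed covariate profile — the age trajectories
#' typically displayed for health-expectancy results.
#'
#' @inheritParams life_expectancies
#' @param ages Vector of starting ages.
#' @return A tibble with columns `start_age`, `state`
#'   (`unmet` / `met`), `years`, `pct_of_total`.
#' @export
marginal_le_by_age <- function(object, panel = NULL, z = covariate_profile(),
                               ages = seq(50, 90, by = 5), h = 0.5,
                               max_age = 115, pi = NULL,
                               include_covariates = FALSE) {
  purrr::map_dfr(ages, function(a) {
    le <- life_expectancies(object, panel, z, start_age = a, h = h,
                            max_age = max_age, pi = pi,
                            include_covariates = include_covariates)
    tibble::tibble(
      start_age = a,
      state = c("unmet", "met"),
      years = c(le$marginal_unmet, le$marginal_met),
      pct_of_total = c(le$pct_unmet, 100 - le$pct_unmet)
    )
  })
}

#' Plot marginal life expectancies by starting age
#'
#' @param data Output of [marginal_le_by_age()].
#' @return A ggplot of marginal life expectancy against starting age by
#'   needs state.
#' @export
plot_marginal_le <- function(data) {
  ggplot2::ggplot(data, ggplot2::aes(x = .data$start_age, y = .data$years,
                                     colour = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "age (years)", y = "marginal life expectancy (years)",
                  colour = "needs state") +
    ggplot2::theme_minimal()
}
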