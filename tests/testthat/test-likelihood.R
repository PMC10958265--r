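test_that("matrix exponential matches limits and the ODE oracle", {
  Q <- raw_generator(0.4, 0.05, 0.2, 0.02)
  expect_equal(unname(expm_probability(Q, 0)), diag(3))
  expect_error(expm_probability(Q, -1), "non-negative")

  # scalar closed form: only met -> dead at rate 0.1
  Q1 <- raw_generator(0, 0, 0, 0.1)
  P <- expm_probability(Q1, 2)
  expect_equal(P[2, 3], 1 - exp(-0.2), tolerance = 1e-12)
  expect_equal(P[2, 3], 0.1812692, tolerance = 1e-6)
  expect_equal(P[1, 1], 1)

  set.seed(7)
  for (i in 1:20) {
    q <- exp(runif(4, log(1e-3), log(2)))
    Q <- raw_generator(q[1], q[2], q[3], q[4])
    P <- expm_probability(Q, 2)
    expect_lt(max(abs(P - ode_probability(Q, 2))), 1e-8)
    # independent general-purpose matrix exponential
    expect_lt(max(abs(P - as.matrix(Matrix::expm(Matrix::Matrix(2 * Q))))),
              1e-10)
    expect_true(all(P >= 0 & P <= 1))
    expect_true(all(abs(rowSums(P) - 1) < 1e-10))
  }
})

test_that("interval probabilities obey limits, Chapman-Kolmogorov and O(h^2) convergence", {
  p <- gompertz_params()
  z <- covariate_profile()
  expect_equal(unname(interval_probability(p, z, 70, 70)), diag(3))

  # time-homogeneous shortcut is exact
  ph <- toy_params()
  expect_equal(interval_probability(ph, z, 60, 65, h = 1),
               expm_probability(build_generator(ph, 60), 5),
               tolerance = 1e-14)

  # Chapman-Kolmogorov at a band boundary
  A <- interval_probability(p, z, 60, 64, h = 1)
  B <- interval_probability(p, z, 60, 62, h = 1) %*%
    interval_probability(p, z, 62, 64, h = 1)
  expect_lt(max(abs(A - B)), 1e-10)

  # midpoint banding converges at second order to the exact solution
  exact <- ode_interval_probability(p, z, 60, 64)
  err <- sapply(c(2, 1, 0.5), function(h) {
    max(abs(interval_probability(p, z, 60, 64, h = h) - exact))
  })
  expect_true(all(diff(err) < 0))
  ratio <- err[-length(err)] / err[-1]
  expect_true(all(ratio > 2.5 & ratio < 6))
})

test_that("death probability is non-decreasing in interval length", {
  p <- toy_params()
  z <- covariate_profile()
  pdead <- sapply(seq(0.5, 10, by = 0.5), function(t) {
    interval_probability(p, z, 60, 60 + t)[2, 3]
  })
  expect_true(all(diff(pdead) > 0))
})

test_that("pair likelihood handles living, death and censored endpoints", {
  p <- gompertz_params()
  z <- covariate_profile()

  expect_equal(pair_log_likelihood(p, 2L, 2L, 60, 60, z), 0)
  expect_error(pair_log_likelihood(p, 3L, 2L, 60, 62, z), "living state")

  # case (a) equals the interval probability entry
  P <- interval_probability(p, z, 60, 62, h = 1)
  expect_equal(pair_log_likelihood(p, 2L, 1L, 60, 62, z), log(P[2, 1]),
               tolerance = 1e-12)

  # censored endpoint sums the living destinations
  expect_equal(pair_log_likelihood(p, 1L, NA, 60, 62, z),
               log(P[1, 1] + P[1, 2]), tolerance = 1e-12)

  # interval-censored death is the death-column entry
  expect_equal(pair_log_likelihood(p, 2L, 3L, 60, 62, z,
                                   death_date_known = 0L),
               log(P[2, 3]), tolerance = 1e-12)

  # exact death density identity: d/dt P_{r3}(t) = sum_s P_{rs}(t) q_{s3}(t)
  dt <- 1e-4
  for (from in 1:2) {
    dens <- exp(pair_log_likelihood(p, from, 3L, 60, 62, z, h = 0.01))
    fd <- (ode_interval_probability(p, z, 60, 62 + dt)[from, 3] -
             ode_interval_probability(p, z, 60, 62 - dt)[from, 3]) / (2 * dt)
    expect_equal(dens, fd, tolerance = 1e-5)
  }
})

test_that("case (a) probabilities match Monte-Carlo trajectory frequencies", {
  p <- toy_params(0.45, 0.12, 0.03, 0.015)
  z <- covariate_profile()
  n <- 50000
  set.seed(99)
  arr <- needstates:::param_arrays(p)
  Z <- matrix(0, n, 5)
  res <- needstates:::sim_interval(arr, Z, rep(60, n), rep(62, n),
                                   rep(1L, n), 0.01)
  P <- interval_probability(p, z, 60, 62)
  for (s in 1:3) {
    phat <- mean(res$state == s)
    se <- sqrt(P[1, s] * (1 - P[1, s]) / n)
    expect_lt(abs(phat - P[1, s]), 3 * se + 1e-4)
  }
})

test_that("the total -2 log-likelihood is additive over subjects and pairs", {
  p <- gompertz_params()
  one_pair <- dplyr::bind_rows(panel_rows("A", 1, 60, 2),
                               panel_rows("A", 2, 62, 1))
  expect_equal(total_neg2_loglik(one_pair, p),
               -2 * pair_log_likelihood(p, 2L, 1L, 60, 62,
                                        covariate_profile()),
               tolerance = 1e-12)

  panel <- simulate_cohort(sim_config(n_subjects = 60), seed = 21)
  panel <- impute_death_dates(panel, seed = 22)
  total <- total_neg2_loglik(panel, p)
  per_subject <- sum(sapply(unique(panel$subject_id), function(s) {
    sub <- panel[panel$subject_id == s, , drop = FALSE]
    if (nrow(sub) < 2) 0 else total_neg2_loglik(sub, p)
  }))
  expect_equal(total, per_subject, tolerance = 1e-8)
})

test_that("panel likelihood matches a fine-grained ODE evaluation", {
  # tiny panel evaluated against the exact (ODE-integrated) interval
  # probabilities instead of the banded approximation
  p <- gompertz_params()
  z <- covariate_profile()
  panel <- dplyr::bind_rows(
    panel_rows("A", 1, 61, 2), panel_rows("A", 2, 63.1, 1),
    panel_rows("A", 3, 64.9, 2),
    panel_rows("B", 1, 72, 1), panel_rows("B", 2, 73.6, 3,
                                          death_date_known = 1),
    panel_rows("C", 1, 80, 2), panel_rows("C", 2, 82, NA)
  )
  ll <- 0
  PA1 <- ode_interval_probability(p, z, 61, 63.1)
  PA2 <- ode_interval_probability(p, z, 63.1, 64.9)
  PB <- ode_interval_probability(p, z, 72, 73.6)
  PC <- ode_interval_probability(p, z, 80, 82)
  ll <- log(PA1[2, 1]) + log(PA2[1, 2]) +
    log(PB[1, 1] * transition_intensity(p, "1-3", 73.6) +
          PB[1, 2] * transition_intensity(p, "2-3", 73.6)) +
    log(PC[2, 1] + PC[2, 2])
  expect_equal(total_neg2_loglik(panel, p, h = 0.05), -2 * ll,
               tolerance = 1e-6)
})
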