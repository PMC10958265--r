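test_that("occupancy grids are proper distributions with monotone mortality", {
  p <- gompertz_params()
  grid <- occupancy(p, start_age = 60, h = 0.5, max_age = 115)
  expect_equal(grid$age[1], 60)
  expect_equal(grid$age[nrow(grid)], 115)
  expect_true(all(abs(grid$p11 + grid$p12 + grid$p13 - 1) < 1e-12))
  expect_true(all(abs(grid$p21 + grid$p22 + grid$p23 - 1) < 1e-12))
  expect_true(all(diff(grid$p13) >= -1e-12))
  expect_true(all(diff(grid$p23) >= -1e-12))

  # negligible intensities: the start state keeps probability one
  frozen <- msm_params(msm_spec(covariates = NULL, age = FALSE),
                       baseline = c("1-2" = -50, "2-1" = -50,
                                    "1-3" = -50, "2-3" = -50))
  g0 <- occupancy(frozen, start_age = 60, h = 1, max_age = 115)
  expect_true(all(abs(g0$p11 - 1) < 1e-12))
  expect_true(all(abs(g0$p22 - 1) < 1e-12))
})

test_that("life expectancy reproduces the truncated-exponential closed form", {
  # single living state with constant death hazard 0.05/year from age 60,
  # truncated at 115: (1 - exp(-55 * 0.05)) / 0.05 years
  lam <- 0.05
  p <- msm_params(msm_spec(covariates = NULL, age = FALSE),
                  baseline = c("1-2" = -50, "2-1" = -50, "1-3" = -50,
                               "2-3" = log(lam)))
  grid <- occupancy(p, start_age = 60, h = 0.02, max_age = 115)
  surv <- exp(-lam * (grid$age - 60))
  expect_lt(max(abs(grid$p22 - surv)), 1e-8)
  e22 <- state_specific_le(grid, 2, 2)
  closed <- (1 - exp(-lam * 55)) / lam
  expect_equal(e22, closed, tolerance = 1e-6)
  expect_equal(e22, 18.721, tolerance = 1e-4)

  # zero hazards: residence time is the truncation bound
  frozen <- msm_params(msm_spec(covariates = NULL, age = FALSE),
                       baseline = c("1-2" = -50, "2-1" = -50,
                                    "1-3" = -50, "2-3" = -50))
  gz <- occupancy(frozen, start_age = 60, h = 0.5, max_age = 115)
  expect_equal(state_specific_le(gz, 2, 2), 55, tolerance = 1e-8)
})

test_that("state-specific expectancies add up to total survival time", {
  p <- gompertz_params()
  grid <- occupancy(p, start_age = 60, h = 0.25, max_age = 115)
  for (r in 1:2) {
    alive <- grid[[paste0("p", r, "1")]] + grid[[paste0("p", r, "2")]]
    total_r <- sum(diff(grid$age) * (head(alive, -1) + tail(alive, -1)) / 2)
    expect_equal(state_specific_le(grid, r, 1) + state_specific_le(grid, r, 2),
                 total_r, tolerance = 1e-10)
  }
})

test_that("halving the grid step converges at second order", {
  p <- gompertz_params()
  e <- sapply(c(1, 0.5, 0.25), function(h) {
    state_specific_le(occupancy(p, start_age = 60, h = h, max_age = 115), 2, 2)
  })
  d1 <- abs(e[1] - e[2])
  d2 <- abs(e[2] - e[3])
  expect_lt(d2, d1)
  expect_gt(d1 / d2, 2.5)
  expect_lt(d1 / d2, 6)
  # h = 0.5 against a dense-grid reference
  ref <- state_specific_le(occupancy(p, start_age = 60, h = 0.005,
                                     max_age = 115), 2, 2)
  expect_lt(abs(e[2] - ref), 0.01)
})

test_that("the baseline state distribution is a proper logistic-in-age fit", {
  set.seed(61)
  n <- 4000
  ages <- runif(n, 45, 85)
  p1 <- plogis(-3 + 0.02 * ages)
  panel <- panel_rows(sprintf("S%04d", 1:n), 1, ages,
                      ifelse(runif(n) < p1, 1L, 2L))
  for (a in c(55, 75)) {
    pi <- initial_state_distribution(panel, a)
    expect_equal(sum(pi), 1)
    expect_lt(abs(pi[["pi_1"]] - plogis(-3 + 0.02 * a)), 0.04)
  }
  all_met <- panel_rows(c("A", "B"), 1, c(60, 65), c(2L, 2L))
  expect_warning(pi0 <- initial_state_distribution(all_met, 60), "degenerate")
  expect_equal(unname(pi0), c(0, 1))
})

test_that("life-expectancy identities hold exactly by construction", {
  p <- gompertz_params()
  le <- life_expectancies(p, z = covariate_profile(), start_age = 60,
                          pi = c(0.2, 0.8))
  expect_equal(le$total, le$marginal_unmet + le$marginal_met)
  expect_equal(le$marginal_unmet, 0.2 * le$e_11 + 0.8 * le$e_21)
  expect_equal(le$pct_unmet, 100 * le$marginal_unmet / le$total)
  expect_lte(le$total, 55)
  expect_true(all(c(le$e_11, le$e_12, le$e_21, le$e_22) >= 0))

  # worked identity on reported-scale numbers
  expect_equal(round(pct_unmet(4.2, 23.6), 1), 17.8)
})

test_that("raising death intensities shortens life expectancy", {
  base <- gompertz_params()
  harsher <- msm_params(
    msm_spec(covariates = NULL, age = TRUE),
    baseline = c("1-2" = log(0.5), "2-1" = log(0.12),
                 "1-3" = log(0.015) + 0.5, "2-3" = log(0.01) + 0.5),
    age = c("1-2" = 0.01, "2-1" = -0.005, "1-3" = 0.07, "2-3" = 0.09)
  )
  le0 <- life_expectancies(base, pi = c(0.2, 0.8))
  le1 <- life_expectancies(harsher, pi = c(0.2, 0.8))
  expect_lt(le1$total, le0$total)

  # when unmet needs carry the higher death intensity, starting unmet
  # cannot lengthen survival
  risky1 <- msm_params(msm_spec(covariates = NULL, age = FALSE),
                       baseline = c("1-2" = log(0.2), "2-1" = log(0.1),
                                    "1-3" = log(0.1), "2-3" = log(0.02)))
  le <- life_expectancies(risky1, pi = c(0.5, 0.5))
  expect_lte(le$e_11 + le$e_12, le$e_21 + le$e_22)
})

test_that("simulation intervals collapse with zero covariance and widen with it", {
  cfg <- sim_config(n_subjects = 500, params = recovery_params())
  panel <- simulate_cohort(cfg, seed = 71)
  panel <- impute_death_dates(panel, seed = 72)
  fit <- suppressWarnings(fit_msm(panel, recovery_spec()))

  fit0 <- fit
  fit0$vcov <- matrix(0, fit$k, fit$k)
  ci0 <- le_confidence_intervals(fit0, panel, start_age = 60, B = 50,
                                 seed = 5)
  expect_equal(ci0$conf.low, ci0$estimate, tolerance = 1e-8)
  expect_equal(ci0$conf.high, ci0$estimate, tolerance = 1e-8)

  ci <- le_confidence_intervals(fit, panel, start_age = 60, B = 200, seed = 6)
  expect_true(all(ci$conf.low <= ci$conf.high))

  # delta-method check in a small-noise regime: quadrupling the
  # covariance of a smooth toy fit roughly doubles interval widths
  toy <- structure(list(params = gompertz_params(),
                        spec = msm_spec(covariates = NULL, age = TRUE),
                        vcov = diag(0.004^2, 8), k = 8, h = 1,
                        death_convention = "exact"),
                   class = "msm_fit")
  ci1 <- le_confidence_intervals(toy, pi = c(0.2, 0.8), start_age = 60,
                                 B = 800, seed = 6)
  toy4 <- toy
  toy4$vcov <- 4 * toy$vcov
  ci4 <- le_confidence_intervals(toy4, pi = c(0.2, 0.8), start_age = 60,
                                 B = 800, seed = 6)
  ratio <- (ci4$conf.high - ci4$conf.low) / (ci1$conf.high - ci1$conf.low)
  expect_true(all(ratio > 1.6 & ratio < 2.5))
})

test_that("marginal life expectancies decline with starting age", {
  p <- gompertz_params()
  by_age <- marginal_le_by_age(p, ages = c(60, 70, 80), pi = c(0.2, 0.8))
  expect_equal(nrow(by_age), 6)
  met <- by_age[by_age$state == "met", ]
  expect_true(all(diff(met$years) < 0))
  gg <- plot_marginal_le(by_age)
  expect_s3_class(gg, "ggplot")
})
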