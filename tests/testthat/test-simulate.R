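test_that("trajectories honour degenerate and closed-form regimes", {
  frozen <- msm_params(msm_spec(covariates = NULL, age = FALSE),
                       baseline = c("1-2" = -50, "2-1" = -50,
                                    "1-3" = -50, "2-3" = -50))
  set.seed(81)
  traj <- simulate_trajectory(frozen, start_age = 60, start_state = 2L,
                              end_age = 70)
  expect_equal(nrow(traj), 0)

  # death-only model: death ages are exponential around the start age
  lam <- 0.3
  p <- msm_params(msm_spec(covariates = NULL, age = FALSE),
                  baseline = c("1-2" = -50, "2-1" = -50, "1-3" = -50,
                               "2-3" = log(lam)))
  n <- 4000
  set.seed(82)
  res <- needstates:::sim_interval(needstates:::param_arrays(p),
                                   matrix(0, n, 5), rep(60, n), rep(90, n),
                                   rep(2L, n), 0.01)
  waits <- res$death_age[!is.na(res$death_age)] - 60
  expect_gt(length(waits), 3500)
  ks <- stats::ks.test(waits, "pexp", rate = lam)
  expect_gt(ks$p.value, 0.01)
})

test_that("homogeneous trajectory frequencies match the matrix exponential", {
  p <- toy_params(0.45, 0.12, 0.03, 0.015)
  n <- 20000
  set.seed(83)
  res <- needstates:::sim_interval(needstates:::param_arrays(p),
                                   matrix(0, n, 5), rep(60, n), rep(62, n),
                                   rep(2L, n), 0.01)
  P <- expm_probability(build_generator(p, 60), 2)
  for (s in 1:3) {
    se <- sqrt(P[2, s] * (1 - P[2, s]) / n)
    expect_lt(abs(mean(res$state == s) - P[2, s]), 3 * se + 1e-4)
  }
})

test_that("wave observation records trajectories faithfully", {
  p <- gompertz_params()
  set.seed(84)
  ids <- sprintf("T%02d", 1:12)
  baseline <- panel_rows(ids, 1, runif(12, 50, 75),
                         sample(1:2, 12, replace = TRUE))
  trajectories <- lapply(seq_along(ids), function(i) {
    simulate_trajectory(p, start_age = baseline$age[i],
                        start_state = baseline$state[i],
                        end_age = baseline$age[i] + 5)
  })
  names(trajectories) <- ids

  cfg <- sim_config(n_subjects = 12, p_dropout = 0, wave_jitter = 0,
                    p_death_date_missing = 0, p_state_missing = 0)
  panel <- observe_panel(trajectories, baseline, cfg, seed = 85)
  expect_equal(nrow(validate_panel(panel)), 0)
  # every living record matches the trajectory state at that age
  for (i in seq_along(ids)) {
    rows <- panel[panel$subject_id == ids[i] & !is.na(panel$state) &
                    panel$state != 3L, ]
    traj <- trajectories[[ids[i]]]
    for (j in seq_len(nrow(rows))) {
      ev <- traj[traj$age <= rows$age[j] & traj$new_state != 3L, ]
      want <- if (nrow(ev) == 0) baseline$state[i] else
        ev$new_state[nrow(ev)]
      expect_equal(rows$state[j], want)
    }
  }

  # masked deaths are reported at the wave with an unknown date
  traj_dead <- list(A = tibble::tibble(age = 61.3, new_state = 3L))
  base_dead <- panel_rows("A", 1, 60, 2)
  cfg_mask <- sim_config(n_subjects = 1, p_dropout = 0, wave_jitter = 0,
                         p_death_date_missing = 1, p_state_missing = 0)
  pd <- observe_panel(traj_dead, base_dead, cfg_mask, seed = 86)
  last <- pd[nrow(pd), ]
  expect_equal(last$state, 3L)
  expect_equal(last$death_date_known, 0L)
  expect_equal(last$age, 62)

  cfg_exact <- sim_config(n_subjects = 1, p_dropout = 0, wave_jitter = 0,
                          p_death_date_missing = 0, p_state_missing = 0)
  pe <- observe_panel(traj_dead, base_dead, cfg_exact, seed = 87)
  expect_equal(pe$age[nrow(pe)], 61.3)
  expect_equal(pe$death_date_known[nrow(pe)], 1L)
})

test_that("simulated cohorts are valid panels with ground truth attached", {
  panel <- simulate_cohort(sim_config(n_subjects = 3000), seed = 88)
  expect_equal(nrow(validate_panel(panel)), 0)
  expect_s3_class(attr(panel, "truth"), "msm_params")
  expect_equal(length(unique(panel$subject_id)), 3000)
  # covariate marginals near their configured proportions
  base <- panel[!duplicated(panel$subject_id), ]
  expect_equal(mean(base$female), 0.509, tolerance = 0.05)
  expect_equal(mean(base$multi_P), 0.456, tolerance = 0.05)

  # raising dropout reduces observed pairs
  lo <- simulate_cohort(sim_config(n_subjects = 1500, p_dropout = 0.05),
                        seed = 89)
  hi <- simulate_cohort(sim_config(n_subjects = 1500, p_dropout = 0.40),
                        seed = 89)
  expect_gt(panel_summary(lo)$n_pairs, panel_summary(hi)$n_pairs)
})

test_that("death-date imputation draws uniformly inside the censoring interval", {
  panel <- simulate_cohort(sim_config(n_subjects = 800), seed = 90)
  none_masked <- panel[!(panel$state %in% 3L) | panel$death_date_known == 1L, ]
  unchanged <- impute_death_dates(none_masked, seed = 91)
  expect_equal(unchanged$age, none_masked$age)
  expect_false(any(unchanged$death_imputed))

  masked <- dplyr::bind_rows(
    panel_rows("M", 1, 62.0, 2),
    panel_rows("M", 2, 64.1, 3, death_date_known = 0)
  )
  draws <- sapply(1:2000, function(i) {
    impute_death_dates(masked, seed = i)$age[2]
  })
  expect_true(all(draws > 62.0 & draws < 64.1))
  ks <- stats::ks.test(draws, "punif", min = 62.0, max = 64.1)
  expect_gt(ks$p.value, 0.01)

  # deterministic under a fixed seed, and flagged as imputed
  a <- impute_death_dates(masked, seed = 7)
  b <- impute_death_dates(masked, seed = 7)
  expect_identical(a$age, b$age)
  expect_true(a$death_imputed[2])
  expect_equal(a$death_date_known[2], 1L)

  orphan <- panel_rows("O", 1, 70, 3, death_date_known = 0)
  expect_error(impute_death_dates(orphan), "no prior observation")
})
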