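#' Configuration for synthetic ageing-cohort generation
#'
#' Bundles the generating conditions for [simulate_cohort()]. Defaults
#' emulate a three-wave ageing cohort followed every two years from
#' baseline ages 45+: covariate marginals of 50.9% female, 67% low /
#' 23% middle / 10% high education, 45.6% physical and 8.3%
#' physical-mental multimorbidity; baseline unmet-needs prevalence
#' around 17% with a mild logistic age gradient; wave follow-up roughly
#' two years apart with interview-timing jitter; per-wave dropout
#' matching follow-up rates near 83%; and a fraction of deaths whose
#' date is unreported (masked to the reporting wave).
#'
#' @param n_subjects Number of subjects.
#' @param params Generating `msm_params`; defaults to
#'   [ageing_cohort_params()].
#' @param age_range Baseline age range (uniform draw), years.
#' @param baseline_logit `c(intercept, slope)` of the logit of baseline
#'   unmet-needs probability in `age - 60`.
#' @param p_female Probability of `female = 1`.
#' @param p_edu Probabilities of low/middle/high education (sums to 1).
#' @param p_multi Probabilities of none/P/PM multimorbidity (sums to 1).
#' @param wave_offsets Scheduled wave times in years from baseline.
#' @param wave_jitter Half-width (years) of uniform interview-timing
#'   jitter applied to follow-up waves.
#' @param p_dropout Per-follow-up-wave dropout probability (absorbing:
#'   a subject lost at one wave is not observed later).
#' @param p_death_date_missing Probability that a death's date is
#'   unreported, so only vital status at the reporting wave is recorded.
#' @param p_state_missing Probability that a living follow-up record has
#'   an unknown needs state (alive, right-censored state).
#' @param sim_band Internal band width (years) of the trajectory
#'   sampler.
#' @param max_age Truncation age for trajectories.
#' @param time_varying_multi Let multimorbidity progress between waves?
#' @param p_progression `c(none_to_P, P_to_PM)` per-wave progression
#'   probabilities, used when `time_varying_multi` is `TRUE`.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 2000,
                       params = ageing_cohort_params(),
                       age_range = c(45, 85),
                       baseline_logit = c(qlogis(0.172), 0.01),
                       p_female = 0.509,
                       p_edu = c(low = 0.67, mid = 0.23, high = 0.10),
                       p_multi = c(none = 0.461, P = 0.456, PM = 0.083),
                       wave_offsets = c(0, 2, 4),
                       wave_jitter = 0.25,
                       p_dropout = 0.17,
                       p_death_date_missing = 0.25,
                       p_state_missing = 0.05,
                       sim_band = 0.01,
                       max_age = 115,
                       time_varying_multi = FALSE,
                       p_progression = c(none_to_P = 0.05, P_to_PM = 0.02)) {
  stopifnot(n_subjects >= 1, diff(range(wave_offsets)) > 0,
            all(diff(wave_offsets) > 0),
            abs(sum(p_edu) - 1) < 1e-8, abs(sum(p_multi) - 1) < 1e-8,
            sim_band > 0)
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

## Vectorised competing-risks simulation of the living process over one
## age interval per subject, intensities frozen over internal bands:
## within each band, exponential waiting times are drawn for each
## allowed transition and the minimum taken; an event within the band
## width is applied and the next band started from the new state.
sim_interval <- function(arr, Z, age0, age1, state0, band) {
  n <- length(age0)
  state <- as.integer(state0)
  death_age <- rep(NA_real_, n)
  k <- 0L
  repeat {
    cur <- age0 + k * band
    active <- state != 3L & cur < age1 - 1e-12
    if (!any(active)) break
    # within the band, living-state flips restart the competing-risks
    # draw from the event time in the new state, so the band scheme is
    # exact for frozen intensities
    live <- which(active)
    sub_start <- cur[live]
    sub_w <- pmin(band, age1[live] - cur[live])
    while (length(live) > 0) {
      mid <- sub_start + sub_w / 2
      q <- intensity_rows(arr, mid, Z[live, , drop = FALSE])
      s1 <- state[live] == 1L
      q_move <- ifelse(s1, q[, "1-2"], q[, "2-1"])
      q_die <- ifelse(s1, q[, "1-3"], q[, "2-3"])
      t_move <- rexp(length(live)) / q_move
      t_die <- rexp(length(live)) / q_die
      t_min <- pmin(t_move, t_die)
      ev <- t_min < sub_w
      if (!any(ev)) break
      died <- ev & (t_die <= t_move)
      di <- live[died]
      state[di] <- 3L
      death_age[di] <- sub_start[died] + t_min[died]
      flip <- ev & !died
      fi <- live[flip]
      state[fi] <- ifelse(state[fi] == 1L, 2L, 1L)
      sub_start <- sub_start[flip] + t_min[flip]
      sub_w <- sub_w[flip] - t_min[flip]
      live <- fi
    }
    k <- k + 1L
  }
  list(state = state, death_age = death_age)
}

#' Simulate one continuous-time trajectory
#'
#' Exact-to-band simulation of a single subject's path through the
#' three-state process under given parameters, for checking the model
#' machinery against its own generative process. Within each internal
#' band (default width 0.01 years) the intensities are frozen,
#' exponential waiting times are drawn for the allowed transitions out
#' of the current state, and the earliest event inside the band is
#' applied.
#'
#' @param params An `msm_params` object.
#' @param z Covariate profile (0/1 values).
#' @param start_age,start_state Starting age (years) and living state
#'   (1 or 2).
#' @param end_age Simulate up to this age; a subject still alive then is
#'   truncated (no event emitted).
#' @param band Internal band width in years.
#' @return A tibble of events with columns `age` and `new_state`
#'   (possibly zero rows).
#' @export
simulate_trajectory <- function(params, z = covariate_profile(), start_age,
                                start_state = 2L, end_age = 115,
                                band = 0.01) {
  stopifnot(start_state %in% 1:2, end_age > start_age)
  arr <- param_arrays(params)
  Z <- matrix(z[COVARIATE_TERMS], 1, 5)
  events <- list()
  age <- start_age
  state <- as.integer(start_state)
  while (state != 3L && age < end_age - 1e-12) {
    res <- sim_interval(arr, Z, age, pmin(age + band, end_age), state, band)
    if (res$state != state) {
      new_age <- if (res$state == 3L) res$death_age else age + band
      events[[length(events) + 1L]] <-
        tibble::tibble(age = new_age, new_state = res$state)
      state <- res$state
    }
    age <- age + band
  }
  if (length(events) == 0) {
    tibble::tibble(age = numeric(), new_state = integer())
  } else {
    dplyr::bind_rows(events)
  }
}

#' Simulate an interval-censored cohort panel with known ground truth
#'
#' Generates a synthetic ageing cohort from the three-state model and
#' observes it the way a wave-based survey would: continuous-time
#' trajectories are sampled between scheduled interviews, living states
#' are recorded only at attended waves (interval censoring), deaths are
#' reported at the following wave with their date either recorded or
#' masked, a fraction of living follow-up records lose their needs
#' state, and dropout right-censors all later observation. The
#' generating parameters are attached as attribute `"truth"`.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer seed.
#' @return A panel tibble in the [read_panel()] schema (passing
#'   [validate_panel()] by construction), with attributes `truth` (the
#'   generating `msm_params`) and `config`.
#' @export
simulate_cohort <- function(config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_subjects
  arr <- param_arrays(config$params)

  female <- rbinom(n, 1, config$p_female)
  edu <- sample(c("low", "mid", "high"), n, replace = TRUE,
                prob = config$p_edu)
  multi <- sample(c("none", "P", "PM"), n, replace = TRUE,
                  prob = config$p_multi)
  Z <- cbind(female = female,
             edu_mid = as.integer(edu == "mid"),
             edu_high = as.integer(edu == "high"),
             multi_P = as.integer(multi == "P"),
             multi_PM = as.integer(multi == "PM"))

  age0 <- runif(n, config$age_range[1], config$age_range[2])
  p_unmet <- plogis(config$baseline_logit[1] +
                      config$baseline_logit[2] * (age0 - 60))
  state <- ifelse(runif(n) < p_unmet, 1L, 2L)

  n_waves <- length(config$wave_offsets)
  wave_age <- matrix(age0, n, n_waves) +
    matrix(config$wave_offsets, n, n_waves, byrow = TRUE)
  if (n_waves > 1) {
    jit <- matrix(runif(n * (n_waves - 1), -config$wave_jitter,
                        config$wave_jitter), n, n_waves - 1)
    wave_age[, -1] <- wave_age[, -1] + jit
  }

  ids <- sprintf("S%05d", seq_len(n))
  rec <- list()
  add_record <- function(keep, wave, age, st, dd) {
    rec[[length(rec) + 1L]] <<- tibble::tibble(
      subject_id = ids[keep], wave = wave, age = age,
      state = unname(st), death_date_known = dd,
      female = unname(Z[keep, "female"]), edu_mid = unname(Z[keep, "edu_mid"]),
      edu_high = unname(Z[keep, "edu_high"]),
      multi_P = unname(Z[keep, "multi_P"]),
      multi_PM = unname(Z[keep, "multi_PM"])
    )
  }
  add_record(rep(TRUE, n), 1L, wave_age[, 1], state, NA_integer_)

  under_obs <- rep(TRUE, n)   # not dropped out, death not yet reported
  alive <- rep(TRUE, n)
  for (w in seq_len(n_waves)[-1]) {
    attend <- under_obs & (runif(n) >= config$p_dropout)
    under_obs <- attend
    sim_idx <- which(attend & alive)
    if (length(sim_idx) == 0) next
    res <- sim_interval(arr, Z[sim_idx, , drop = FALSE],
                        wave_age[sim_idx, w - 1], wave_age[sim_idx, w],
                        state[sim_idx], config$sim_band)
    state[sim_idx] <- res$state
    died <- sim_idx[res$state == 3L]
    if (length(died) > 0) {
      alive[died] <- FALSE
      under_obs[died] <- FALSE
      masked <- runif(length(died)) < config$p_death_date_missing
      d_age <- res$death_age[res$state == 3L]
      keep <- rep(FALSE, n); keep[died] <- TRUE
      add_record(keep, as.integer(w),
                 ifelse(masked, wave_age[died, w], d_age),
                 3L, as.integer(!masked))
    }
    living <- sim_idx[res$state != 3L]
    if (length(living) > 0) {
      miss <- runif(length(living)) < config$p_state_missing
      keep <- rep(FALSE, n); keep[living] <- TRUE
      add_record(keep, as.integer(w), wave_age[living, w],
                 ifelse(miss, NA_integer_, state[living]), NA_integer_)
    }
    if (config$time_varying_multi) {
      prog1 <- multi == "none" & runif(n) < config$p_progression[1]
      prog2 <- multi == "P" & runif(n) < config$p_progression[2]
      multi[prog1] <- "P"
      multi[prog2] <- "PM"
      Z[, "multi_P"] <- as.integer(multi == "P")
      Z[, "multi_PM"] <- as.integer(multi == "PM")
    }
  }
  panel <- dplyr::arrange(dplyr::bind_rows(rec), .data$subject_id, .data$age)
  attr(panel, "truth") <- config$params
  attr(panel, "config") <- config
  panel
}

#' Observe continuous-time trajectories at survey waves
#'
#' Converts fully known continuous-time trajectories into an
#' interval-censored panel the way a wave-based survey records them:
#' the living state is recorded at each attended wave, a death is
#' reported at the next scheduled wave after it happens (with its date
#' masked to the reporting-wave age with the configured probability),
#' and dropout removes all later observation. [simulate_cohort()] fuses
#' trajectory generation and observation for speed; this standalone
#' operation observes trajectories you supply.
#'
#' @param trajectories A named list (by subject id) of event tibbles as
#'   returned by [simulate_trajectory()].
#' @param baseline A tibble with one row per subject: `subject_id`,
#'   `age` (baseline age), `state` (baseline living state), and the five
#'   covariate columns.
#' @param config A [sim_config()] providing wave offsets, jitter,
#'   dropout and masking probabilities.
#' @param seed Optional integer seed for jitter, dropout and masking.
#' @return A panel tibble in the [read_panel()] schema.
#' @export
observe_panel <- function(trajectories, baseline, config = sim_config(),
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_waves <- length(config$wave_offsets)
  rec <- list()
  for (i in seq_len(nrow(baseline))) {
    id <- baseline$subject_id[i]
    traj <- trajectories[[id]]
    z <- baseline[i, COVARIATE_TERMS]
    wave_ages <- baseline$age[i] + config$wave_offsets
    if (n_waves > 1) {
      wave_ages[-1] <- wave_ages[-1] +
        runif(n_waves - 1, -config$wave_jitter, config$wave_jitter)
    }
    death_age <- if (nrow(traj) > 0 && traj$new_state[nrow(traj)] == 3L) {
      traj$age[nrow(traj)]
    } else {
      Inf
    }
    state_at <- function(a) {
      ev <- traj[traj$age <= a & traj$new_state != 3L, , drop = FALSE]
      if (nrow(ev) == 0) baseline$state[i] else ev$new_state[nrow(ev)]
    }
    row <- function(wave, age, st, dd) {
      tibble::tibble(subject_id = id, wave = wave, age = age,
                     state = st, death_date_known = dd) |>
        dplyr::bind_cols(z)
    }
    rec[[length(rec) + 1L]] <- row(1L, wave_ages[1], baseline$state[i],
                                   NA_integer_)
    for (w in seq_len(n_waves)[-1]) {
      if (runif(1) < config$p_dropout) break
      if (death_age <= wave_ages[w]) {
        masked <- runif(1) < config$p_death_date_missing
        rec[[length(rec) + 1L]] <- row(
          as.integer(w), if (masked) wave_ages[w] else death_age,
          3L, as.integer(!masked)
        )
        break
      }
      st <- state_at(wave_ages[w])
      if (runif(1) < config$p_state_missing) st <- NA_integer_
      rec[[length(rec) + 1L]] <- row(as.integer(w), wave_ages[w],
                                     as.integer(st), NA_integer_)
    }
  }
  dplyr::arrange(dplyr::bind_rows(rec), .data$subject_id, .data$age)
}

#' Impute masked death dates
#'
#' Deaths whose date was unreported carry the reporting-wave age and
#' `death_date_known = 0`. This replaces each such age with a uniform
#' random draw strictly between the subject's previous interview age and
#' the reporting-wave age, marks the record as known
#' (`death_date_known = 1`), and flags it in a new `death_imputed`
#' column. All other records are untouched; the result is deterministic
#' under a fixed seed.
#'
#' @param panel A valid panel tibble.
#' @param seed Optional integer seed.
#' @return The panel with imputed death ages.
#' @export
impute_death_dates <- function(panel, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  panel <- dplyr::arrange(panel, .data$subject_id, .data$age)
  panel$death_imputed <- FALSE
  mask <- which(!is.na(panel$state) & panel$state == 3L &
                  !is.na(panel$death_date_known) &
                  panel$death_date_known == 0L)
  for (i in mask) {
    if (i == 1 || panel$subject_id[i - 1] != panel$subject_id[i]) {
      abort(paste0("masked death with no prior observation: subject ",
                   panel$subject_id[i]))
    }
    lo <- panel$age[i - 1]
    hi <- panel$age[i]
    u <- runif(1)
    panel$age[i] <- lo + (hi - lo) * u
    panel$death_date_known[i] <- 1L
    panel$death_imputed[i] <- TRUE
  }
  panel
}
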