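#' Transition probabilities by multimorbidity group
#'
#' Predicted interval transition probabilities (default: 2 years from
#' age 60) for each multimorbidity group, with the remaining covariates
#' held at supplied dummy means and simulation-based percentile
#' intervals — the layout conventional for reporting how multimorbidity
#' shifts short-term transition risks. Each origin state's three
#' destination probabilities sum to 1.
#'
#' @param fit An `msm_fit`.
#' @param covariate_means Named vector of dummy means for `female`,
#'   `edu_mid`, `edu_high` at which non-multimorbidity covariates are
#'   held.
#' @param age Starting age in years.
#' @param horizon Interval length in years.
#' @param B Parameter draws for the intervals (0 to skip intervals).
#' @param seed Optional seed for the draws.
#' @return A tibble: `multimorbidity`, `from`, `to`, `estimate`, and
#'   `conf.low` / `conf.high` when `B > 0`.
#' @export
transition_probability_table <- function(fit,
                                         covariate_means = c(female = 0.509,
                                                             edu_mid = 0.23,
                                                             edu_high = 0.10),
                                         age = 60, horizon = 2, B = 1000,
                                         seed = NULL) {
  purrr::map_dfr(c("none", "P", "PM"), function(g) {
    z <- covariate_profile(
      female = covariate_means[["female"]],
      edu_mid = covariate_means[["edu_mid"]],
      edu_high = covariate_means[["edu_high"]],
      multi_P = as.numeric(g == "P"),
      multi_PM = as.numeric(g == "PM")
    )
    p <- predict_transition_probabilities(fit, z, age, horizon,
                                          ci = B > 0, B = max(B, 2),
                                          seed = seed)
    dplyr::bind_cols(tibble::tibble(multimorbidity = g), p)
  })
}

#' Unadjusted and adjusted hazard-ratio report
#'
#' The covariate-effect table of the analysis: adjusted hazard ratios
#' from the full fit, and optionally unadjusted ones obtained by
#' refitting single-term specifications (each covariate alone on all
#' transitions; age alone for the age row) through the same likelihood
#' machinery.
#'
#' @param panel The panel the fit was estimated from (needed for
#'   unadjusted refits).
#' @param fit An `msm_fit` under the full specification.
#' @param unadjusted Also fit single-covariate models?
#' @param h,death_convention Passed to the unadjusted refits; default to
#'   the fit's settings.
#' @return A tibble with columns `transition`, `term`, `model`
#'   (`adjusted` / `unadjusted`), `hr`, `ci_low`, `ci_high`, `se_log`.
#' @export
hazard_ratio_report <- function(panel, fit, unadjusted = FALSE,
                                h = fit$h,
                                death_convention = fit$death_convention) {
  adj <- hazard_ratio_table(fit)
  adj$model <- "adjusted"
  out <- adj
  if (unadjusted) {
    terms <- unique(unlist(fit$spec$covariates))
    unadj <- purrr::map_dfr(c(if (any(unlist(fit$spec$age))) "age", terms),
      function(tm) {
        spec1 <- if (tm == "age") {
          msm_spec(covariates = NULL, age = TRUE, age_ref = fit$spec$age_ref)
        } else {
          msm_spec(covariates = tm, age = FALSE, age_ref = fit$spec$age_ref)
        }
        f1 <- fit_msm(panel, spec1, h = h, death_convention = death_convention)
        hazard_ratio_table(f1)
      })
    unadj$model <- "unadjusted"
    out <- dplyr::bind_rows(out, unadj)
  }
  dplyr::arrange(out, .data$transition, .data$term,
                 dplyr::desc(.data$model))
}

#' Life-expectancy report across covariate profiles
#'
#' Total, marginal and state-specific residual life expectancies with
#' simulation intervals for a set of labelled covariate profiles and
#' starting ages.
#'
#' @param fit An `msm_fit` with a covariance matrix.
#' @param panel Panel used for the baseline state distribution.
#' @param profiles A named list of covariate profiles (see
#'   [covariate_profile()]); names label the rows.
#' @param ages Starting ages in years.
#' @param h,max_age,B,seed Passed to [le_confidence_intervals()].
#' @return A tibble: `profile`, `start_age`, `quantity`, `estimate`,
#'   `conf.low`, `conf.high`.
#' @export
life_expectancy_report <- function(fit, panel, profiles, ages = 60,
                                   h = 0.5, max_age = 115, B = 1000,
                                   seed = NULL) {
  grid <- tidyr::expand_grid(profile = names(profiles), start_age = ages)
  purrr::map2_dfr(grid$profile, grid$start_age, function(p, a) {
    ci <- le_confidence_intervals(fit, panel, z = profiles[[p]],
                                  start_age = a, B = B, seed = seed,
                                  h = h, max_age = max_age)
    dplyr::bind_cols(tibble::tibble(profile = p, start_age = a), ci)
  })
}

#' Run the full analysis pipeline on a panel
#'
#' Orchestrates the end-to-end analysis: validate the panel, impute
#' masked death dates, fit the multistate model, predict transition
#' probabilities by multimorbidity group, and estimate life expectancies
#' with simulation intervals. All outputs are returned and, if
#' `out_dir` is given, written as CSV files alongside a plain-text log
#' recording sample sizes, the transition count table, convergence
#' diagnostics, the seed, and a configuration hash.
#'
#' @param panel A panel tibble, e.g. from [simulate_cohort()] or
#'   [read_panel()].
#' @param spec Model specification (default: full model).
#' @param out_dir Optional output directory (created if missing).
#' @param seed Integer seed for the stochastic stages (death-date
#'   imputation and simulation intervals).
#' @param h_lik,h_le Band widths in years for likelihood and
#'   life-expectancy integration.
#' @param max_age Truncation age for life expectancies.
#' @param B Parameter draws for all simulation intervals.
#' @param le_ages Starting ages for the life-expectancy report.
#' @param death_convention Passed to [fit_msm()].
#' @return A list with components `panel`, `fit`, `hr`,
#'   `transition_probs`, `life_expectancy`, `log` (character vector),
#'   invisibly.
#' @export
run_full_pipeline <- function(panel, spec = msm_spec(), out_dir = NULL,
                              seed = 1L, h_lik = 1, h_le = 0.5,
                              max_age = 115, B = 500, le_ages = 60,
                              death_convention = "exact") {
  log_lines <- c(
    paste0("needstates pipeline, seed = ", seed),
    paste0("config hash: ",
           rlang::hash(list(spec, h_lik, h_le, max_age, B, le_ages,
                            death_convention)))
  )
  report <- validate_panel(panel)
  if (nrow(report) > 0) {
    abort(paste0("stage `validate`: panel has ", nrow(report),
                 " violation(s); first: [", report$rule[1], "] subject ",
                 report$subject_id[1]))
  }
  ps <- panel_summary(panel)
  log_lines <- c(log_lines,
                 sprintf("subjects: %d (single-observation: %d), pairs: %d",
                         ps$n_subjects, ps$n_single, ps$n_pairs))
  n_masked <- sum(panel$state == 3L & panel$death_date_known == 0L,
                  na.rm = TRUE)
  panel <- impute_death_dates(panel, seed = seed)
  log_lines <- c(log_lines, sprintf("imputed death dates: %d", n_masked))
  counts <- transition_count_table(panel)
  log_lines <- c(log_lines, "transition count table:",
                 utils::capture.output(print(counts)))

  fit <- fit_msm(panel, spec, h = h_lik, death_convention = death_convention)
  log_lines <- c(log_lines,
                 sprintf("fit: -2loglik = %.2f, AIC = %.2f, k = %d",
                         fit$minus2loglik, fit$aic, fit$k),
                 sprintf("converged: %s, |gradient| = %.3e, evals = %d",
                         fit$converged, fit$gradient_norm,
                         fit$optim$counts[["function"]]))

  hr <- hazard_ratio_table(fit)
  probs <- transition_probability_table(fit, B = B, seed = seed)
  profiles <- list(
    overall = covariate_profile(female = mean(panel$female),
                                edu_mid = mean(panel$edu_mid),
                                edu_high = mean(panel$edu_high),
                                multi_P = mean(panel$multi_P),
                                multi_PM = mean(panel$multi_PM))
  )
  le <- life_expectancy_report(fit, panel, profiles, ages = le_ages,
                               h = h_le, max_age = max_age, B = B,
                               seed = seed)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_panel(panel, file.path(out_dir, "panel_imputed.csv"))
    readr::write_csv(tidy.msm_fit(fit), file.path(out_dir, "fit_params.csv"))
    readr::write_csv(hr, file.path(out_dir, "hazard_ratios.csv"))
    readr::write_csv(probs, file.path(out_dir, "transition_probs.csv"))
    readr::write_csv(le, file.path(out_dir, "life_expectancy.csv"))
    writeLines(log_lines, file.path(out_dir, "pipeline_log.txt"))
  }
  invisible(list(panel = panel, fit = fit, hr = hr,
                 transition_probs = probs, life_expectancy = le,
                 log = log_lines))
}
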