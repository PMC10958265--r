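#' Read a long-format needs-state panel from CSV
#'
#' Reads interval-censored multistate panel data in the long format used
#' throughout the package: one row per subject-wave with the observed
#' needs state, age at observation, and covariates.
#'
#' The mandatory columns are `subject_id`, `wave`, `age`, `state`,
#' `death_date_known`, `female`, `edu_mid`, `edu_high`, `multi_P`,
#' `multi_PM`. States are coded 1 = unmet healthcare needs, 2 = met
#' healthcare needs, 3 = dead; a missing `state` on a row denotes a
#' subject known to be alive at that age with unknown living state
#' (right-censored). `death_date_known` is meaningful only on state-3
#' rows: 1 if `age` is the (possibly imputed) death age, 0 if `age` is
#' the reporting-wave age and the actual death time is only known to lie
#' in the preceding interval.
#'
#' @param path Path to a comma-separated file with a header row.
#' @param validate If `TRUE` (default), structural violations (see
#'   [validate_panel()]) abort with an informative error.
#' @return A tibble sorted by subject and age, one row per observation.
#' @seealso [validate_panel()], [write_panel()], [simulate_cohort()]
#' @export
read_panel <- function(path, validate = TRUE) {
  header <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols(),
                                  progress = FALSE))
  missing_cols <- setdiff(PANEL_COLUMNS, header)
  if (length(missing_cols) > 0) {
    abort(paste0("Missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  panel <- readr::read_csv(
    path,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      wave = readr::col_integer(),
      age = readr::col_double(),
      state = readr::col_integer(),
      death_date_known = readr::col_integer(),
      .default = readr::col_double()
    ),
    progress = FALSE
  )
  probs <- readr::problems(panel)
  if (nrow(probs) > 0) {
    abort(paste0(
      "Malformed rows in ", path, " (line numbers include the header):\n",
      paste0("  line ", probs$row + 1L, ": expected ", probs$expected,
             ", got ", probs$actual, collapse = "\n")
    ))
  }
  panel <- dplyr::arrange(panel, .data$subject_id, .data$age)
  if (validate) {
    report <- validate_panel(panel)
    if (nrow(report) > 0) {
      abort(paste0(
        "Panel failed validation:\n",
        paste0("  [", report$rule, "] subject ", report$subject_id, ": ",
               report$message, collapse = "\n")
      ))
    }
  }
  panel
}

#' Write a needs-state panel to CSV
#'
#' Inverse of [read_panel()]: writes the long-format schema so that
#' `read_panel(write_panel(panel, path))` reproduces `panel`
#' field-for-field.
#'
#' @param panel A panel tibble (see [read_panel()] for the schema).
#' @param path Output file path.
#' @return `panel`, invisibly.
#' @export
write_panel <- function(panel, path) {
  readr::write_csv(panel[, PANEL_COLUMNS], path, progress = FALSE)
  invisible(panel)
}

#' Structurally validate a needs-state panel
#'
#' Checks the invariants of interval-censored multistate panel data and
#' returns the violations as data rather than raising conditions: state
#' codes in \{1, 2, 3\} (or missing, for alive-with-unknown-state rows),
#' strictly increasing ages within subject, death (state 3) absorbing
#' and final, at most one death record per subject, mutually exclusive
#' education and multimorbidity dummies, and no missing covariate
#' values.
#'
#' @param panel A panel tibble in the [read_panel()] schema.
#' @return A tibble with columns `subject_id`, `rule`, `message`; zero
#'   rows if and only if the panel is valid.
#' @export
validate_panel <- function(panel) {
  viol <- list()
  add <- function(subject_id, rule, message) {
    viol[[length(viol) + 1L]] <<- tibble::tibble(
      subject_id = as.character(subject_id), rule = rule, message = message
    )
  }

  bad_state <- !is.na(panel$state) & !(panel$state %in% c(1L, 2L, 3L))
  for (i in which(bad_state)) {
    add(panel$subject_id[i], "state-code",
        paste0("state ", panel$state[i], " is not in {1, 2, 3}"))
  }

  for (v in COVARIATE_TERMS) {
    na_cov <- is.na(panel[[v]])
    for (s in unique(panel$subject_id[na_cov])) {
      add(s, "covariate-missing", paste0("missing value in `", v, "`"))
    }
    bad01 <- !is.na(panel[[v]]) & !(panel[[v]] %in% c(0, 1))
    for (s in unique(panel$subject_id[bad01])) {
      add(s, "covariate-dummy",
          paste0("`", v, "` must be 0/1 in data records"))
    }
  }
  two_edu <- panel$edu_mid + panel$edu_high > 1
  for (s in unique(panel$subject_id[!is.na(two_edu) & two_edu])) {
    add(s, "education-exclusive", "edu_mid + edu_high exceeds 1")
  }
  two_multi <- panel$multi_P + panel$multi_PM > 1
  for (s in unique(panel$subject_id[!is.na(two_multi) & two_multi])) {
    add(s, "multimorbidity-exclusive", "multi_P + multi_PM exceeds 1")
  }

  by_subject <- split(seq_len(nrow(panel)), panel$subject_id)
  for (s in names(by_subject)) {
    idx <- by_subject[[s]]
    ages <- panel$age[idx]
    states <- panel$state[idx]
    if (any(ages <= 0 | is.na(ages))) {
      add(s, "age-positive", "ages must be positive and non-missing")
    } else if (length(idx) > 1 && any(diff(ages) <= 0)) {
      add(s, "age-monotone", "ages are not strictly increasing")
    }
    dead <- which(!is.na(states) & states == 3L)
    if (length(dead) > 1) {
      add(s, "death-absorbing", "more than one death record")
    } else if (length(dead) == 1 && dead < length(idx)) {
      add(s, "death-absorbing", "observation follows a death record")
    }
    if (length(dead) >= 1 && any(is.na(panel$death_date_known[idx[dead]]))) {
      add(s, "death-date-flag", "death record lacks death_date_known")
    }
  }

  if (length(viol) == 0) {
    tibble::tibble(subject_id = character(), rule = character(),
                   message = character())
  } else {
    dplyr::arrange(dplyr::bind_rows(viol), .data$subject_id, .data$rule)
  }
}

#' Tabulate observed consecutive-wave state transitions
#'
#' Counts ordered pairs of states observed at consecutive waves across
#' all subjects, the raw material for crude transition rates and for the
#' transition-distribution table of a cohort. Pairs involving a missing
#' living state (right-censored rows) are excluded.
#'
#' @param panel A valid panel tibble.
#' @return A 3 by 3 integer matrix `counts[from, to]`; the grand total
#'   equals the number of consecutive observed pairs.
#' @export
transition_count_table <- function(panel) {
  pairs <- panel_pairs(panel)
  keep <- !is.na(pairs$to_state)
  tab <- table(factor(pairs$from_state[keep], levels = 1:3),
               factor(pairs$to_state[keep], levels = 1:3))
  counts <- matrix(as.integer(tab), 3, 3,
                   dimnames = list(from = c("unmet", "met", "dead"),
                                   to = c("unmet", "met", "dead")))
  counts
}

## Consecutive observation pairs of a panel, one row per likelihood
## contribution: covariates are taken from the interval's left endpoint
## (piecewise-constant covariates between waves).
panel_pairs <- function(panel) {
  panel <- dplyr::arrange(panel, .data$subject_id, .data$age)
  n <- nrow(panel)
  same <- panel$subject_id[-n] == panel$subject_id[-1]
  i <- which(same)
  out <- tibble::tibble(
    subject_id = panel$subject_id[i],
    from_state = panel$state[i],
    to_state = panel$state[i + 1L],
    age0 = panel$age[i],
    age1 = panel$age[i + 1L],
    death_date_known = panel$death_date_known[i + 1L]
  )
  for (v in COVARIATE_TERMS) out[[v]] <- panel[[v]][i]
  out
}

#' Count subjects and likelihood-contributing observation pairs
#'
#' Subjects observed exactly once are retained in a panel (they inform
#' baseline prevalence) but contribute no transition pairs.
#'
#' @param panel A valid panel tibble.
#' @return A one-row tibble with `n_subjects`, `n_single` (subjects with
#'   one observation), and `n_pairs`.
#' @export
panel_summary <- function(panel) {
  n_obs <- table(panel$subject_id)
  pairs <- panel_pairs(panel)
  usable <- !is.na(pairs$from_state) & pairs$from_state %in% c(1L, 2L)
  tibble::tibble(
    n_subjects = length(n_obs),
    n_single = sum(n_obs == 1L),
    n_pairs = sum(usable)
  )
}
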