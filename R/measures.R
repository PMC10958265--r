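#' Derive the healthcare-needs state from utilisation indicators
#'
#' A respondent has unmet healthcare needs (state 1) if either trigger
#' fires: they were ill in the last month but used no outpatient care,
#' or inpatient care was recommended in the past year but they were not
#' hospitalised. Otherwise the needs state is met (state 2); respondents
#' with no perceived need (not ill, no inpatient recommendation) are
#' coded met, since only the two triggers define unmet needs.
#'
#' All arguments are logical vectors and are recycled to a common
#' length.
#'
#' @param ill_last_month Ill during the last month?
#' @param outpatient_used Any outpatient care used in the last month?
#' @param inpatient_recommended Inpatient care recommended in the past
#'   year?
#' @param hospitalised Hospitalised in the past year?
#' @return Integer vector of state codes, 1 (unmet) or 2 (met).
#' @examples
#' derive_needs_state(TRUE, FALSE, FALSE, FALSE)  # ill, no outpatient -> 1
#' derive_needs_state(FALSE, FALSE, FALSE, FALSE) # no perceived need -> 2
#' @export
derive_needs_state <- function(ill_last_month, outpatient_used,
                               inpatient_recommended, hospitalised) {
  unmet <- (ill_last_month & !outpatient_used) |
    (inpatient_recommended & !hospitalised)
  ifelse(unmet, 1L, 2L)
}

#' Score the CES-D-10 depression scale
#'
#' Sums the ten item responses (each 0-3, total range 0-30) and applies
#' the conventional cut-off of 10 or more to flag depression.
#'
#' @param items A length-10 integer vector, or a matrix / data frame
#'   with 10 columns (one row per respondent), of item responses in
#'   0..3.
#' @return A tibble with columns `total` (0-30) and `depressed`
#'   (`total >= 10`), one row per respondent.
#' @export
score_cesd10 <- function(items) {
  m <- if (is.data.frame(items)) as.matrix(items) else items
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  if (ncol(m) != 10) {
    abort("CES-D-10 requires exactly 10 item responses per respondent")
  }
  if (anyNA(m) || any(m < 0 | m > 3) || any(m != round(m))) {
    abort("CES-D-10 item responses must be integers in 0..3")
  }
  total <- as.integer(rowSums(m))
  tibble::tibble(total = total, depressed = total >= 10L)
}

#' Default chronic-condition checklist
#'
#' A 14-item list of physician-diagnosed chronic conditions of the kind
#' collected in ageing cohort surveys, with a physical/mental flag per
#' condition. Screening-based depression (CES-D-10 >= 10) is counted as
#' a 15th, mental, condition by [classify_multimorbidity()]. The list is
#' a configurable default: supply your own tibble with columns
#' `condition` and `mental` to match a specific instrument.
#'
#' @return A tibble with columns `condition` (character) and `mental`
#'   (logical).
#' @export
default_condition_list <- function() {
  tibble::tibble(
    condition = c("hypertension", "dyslipidaemia", "diabetes", "cancer",
                  "chronic_lung_disease", "liver_disease", "heart_disease",
                  "stroke", "kidney_disease", "digestive_disease",
                  "psychiatric_problems", "memory_related_disease",
                  "arthritis", "asthma"),
    mental = c(rep(FALSE, 10), TRUE, TRUE, FALSE, FALSE)
  )
}

#' Classify multimorbidity from a condition checklist
#'
#' Groups respondents into `none` / `P` (physical multimorbidity) / `PM`
#' (physical-mental multimorbidity) from their diagnosed conditions plus
#' screening-based depression, which counts as one mental condition.
#'
#' Two classification rules are available, because "two or more
#' conditions in each category" admits two readings:
#' \describe{
#'   \item{`"mixed_pair"` (default)}{`PM` if the total condition count
#'     is at least 2 with at least one physical and one mental
#'     condition; else `P` if there are two or more physical conditions;
#'     else `none`. This follows the common multimorbidity convention
#'     that any co-occurring pair qualifies.}
#'   \item{`"strict_pairs"`}{`PM` requires two or more physical AND two
#'     or more mental conditions; `P` requires two or more physical
#'     conditions.}
#' }
#' Under either rule, respondents whose conditions are exclusively
#' mental and who have no qualifying physical count fall in `none`
#' (mental-only multimorbidity is not a category of this scheme).
#'
#' @param conditions A list (one element per respondent) of character
#'   vectors of condition identifiers, or a single character vector for
#'   one respondent.
#' @param depressed Logical vector: CES-D-10 screening positive?
#' @param condition_list Tibble of known conditions with their
#'   physical/mental flag; see [default_condition_list()].
#' @param rule `"mixed_pair"` or `"strict_pairs"`.
#' @return A factor with levels `none`, `P`, `PM`.
#' @export
classify_multimorbidity <- function(conditions, depressed = FALSE,
                                    condition_list = default_condition_list(),
                                    rule = c("mixed_pair", "strict_pairs")) {
  rule <- match.arg(rule)
  if (!is.list(conditions)) conditions <- list(conditions)
  n <- max(length(conditions), length(depressed))
  conditions <- rep_len(conditions, n)
  depressed <- rep_len(depressed, n)
  mental_set <- condition_list$condition[condition_list$mental]

  out <- character(n)
  for (i in seq_len(n)) {
    cond <- unique(conditions[[i]])
    unknown <- setdiff(cond, condition_list$condition)
    if (length(unknown) > 0) {
      abort(paste0("Unknown condition(s): ", paste(unknown, collapse = ", ")))
    }
    n_ment <- sum(cond %in% mental_set) + as.integer(isTRUE(depressed[i]))
    n_phys <- sum(!(cond %in% mental_set))
    out[i] <- switch(rule,
      mixed_pair = if (n_phys + n_ment >= 2 && n_phys >= 1 && n_ment >= 1) {
        "PM"
      } else if (n_phys >= 2) "P" else "none",
      strict_pairs = if (n_phys >= 2 && n_ment >= 2) {
        "PM"
      } else if (n_phys >= 2) "P" else "none"
    )
  }
  factor(out, levels = c("none", "P", "PM"))
}

#' Expand a multimorbidity category into model dummies
#'
#' @param category A factor or character vector with values `none`, `P`,
#'   `PM`.
#' @return A tibble with 0/1 columns `multi_P` and `multi_PM`
#'   (reference: `none`).
#' @export
multimorbidity_dummies <- function(category) {
  category <- as.character(category)
  stopifnot(all(category %in% c("none", "P", "PM")))
  tibble::tibble(
    multi_P = as.integer(category == "P"),
    multi_PM = as.integer(category == "PM")
  )
}
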