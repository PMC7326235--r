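# Cohort data model: questionnaire records, validation, eligibility filters.

#' Regularity answers recognised in cohort data
#'
#' The three possible answers to "Do you have regular periods?":
#' `"regular"` ("Yes"), `"irregular"` ("No, they have been irregular for a
#' few months") and `"stopped"` ("No, my periods have stopped").
#'
#' @return Character vector of the three regularity levels.
#' @export
regularity_levels <- function() c("regular", "irregular", "stopped")

#' Oophorectomy status levels
#'
#' @return Character vector: `"none"`, `"unilateral"`, `"bilateral"`.
#' @export
oophorectomy_levels <- function() c("none", "unilateral", "bilateral")

#' Exclusion reason codes used by the eligibility filter
#'
#' @return Character vector of the five reason codes.
#' @export
eligibility_reasons <- function() {
  c("HORMONE_USE", "PREGNANT", "BREASTFEEDING", "IRREGULAR_UNRELATED",
    "BILATERAL_OOPHORECTOMY")
}

cohort_columns <- function() {
  c("id", "age", "periods_last_12m", "regularity", "smoker_current",
    "oophorectomy", "exogenous_hormone_use", "pregnant", "breastfeeding",
    "irregular_unrelated_to_menopause", "fsh", "estradiol")
}

#' Construct participant records
#'
#' Builds a cohort data frame (one row per woman) holding the questionnaire
#' answers the score consumes, plus the optional serum hormone panel.
#' Fractional ages are truncated toward zero with a warning, because the
#' development cross-tabulation is by whole year of age.
#'
#' @param id Participant identifiers (character).
#' @param age Age in completed years (integer, >= 0).
#' @param periods_last_12m Number of menstrual periods reported for the last
#'   twelve months (integer, >= 0).
#' @param regularity One of [regularity_levels()] per record.
#' @param smoker_current Logical: currently smoking.
#' @param oophorectomy One of [oophorectomy_levels()] per record.
#' @param exogenous_hormone_use Logical: current use of exogenous sex
#'   hormones (contraceptives, hormone replacement, intermittent progestin).
#' @param pregnant,breastfeeding Logical flags at time of survey.
#' @param irregular_unrelated_to_menopause Logical: irregular menstruation
#'   attributed to a cause other than the menopausal transition.
#' @param fsh Follicle stimulating hormone, IU/L (`NA` if not measured).
#' @param estradiol 17beta-estradiol, pmol/L (`NA` if not measured).
#' @return A `data.frame` with the canonical cohort columns.
#' @examples
#' participant_record("w1", age = 50, periods_last_12m = 12,
#'                    regularity = "regular")
#' @export
participant_record <- function(id, age, periods_last_12m, regularity,
                               smoker_current = FALSE,
                               oophorectomy = "none",
                               exogenous_hormone_use = FALSE,
                               pregnant = FALSE,
                               breastfeeding = FALSE,
                               irregular_unrelated_to_menopause = FALSE,
                               fsh = NA_real_, estradiol = NA_real_) {
  if (any(is.finite(age) & age != trunc(age))) {
    warning("fractional ages truncated toward zero (whole-year model)")
    age <- trunc(age)
  }
  data.frame(
    id = as.character(id),
    age = as.integer(age),
    periods_last_12m = as.integer(periods_last_12m),
    regularity = as.character(regularity),
    smoker_current = as.logical(smoker_current),
    oophorectomy = as.character(oophorectomy),
    exogenous_hormone_use = as.logical(exogenous_hormone_use),
    pregnant = as.logical(pregnant),
    breastfeeding = as.logical(breastfeeding),
    irregular_unrelated_to_menopause = as.logical(irregular_unrelated_to_menopause),
    fsh = as.numeric(fsh),
    estradiol = as.numeric(estradiol),
    stringsAsFactors = FALSE
  )
}

issue <- function(row, field, message, advisory = FALSE) {
  data.frame(row = row, field = field, message = message,
             advisory = advisory, stringsAsFactors = FALSE)
}

#' Validate cohort records
#'
#' Checks each record against the field constraints and returns a data frame
#' of issues; a well-formed cohort yields zero rows. Issues name the
#' offending field. The input is never modified and missing hormone values
#' are never coerced to zero. A record reporting stopped menses together
#' with more than twelve periods is contradictory and flagged as an error;
#' stopped with 1-12 recent periods is permitted (recently stopped menses).
#' A hormone panel with only one of FSH/estradiol present draws an advisory
#' issue: scoring ignores the pair rather than using half of it.
#'
#' @param cohort Cohort data frame as from [participant_record()] or
#'   [read_cohort_csv()].
#' @return Data frame with columns `row`, `field`, `message`, `advisory`.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  missing_cols <- setdiff(cohort_columns(), names(cohort))
  if (length(missing_cols) > 0) {
    stop("cohort is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  issues <- list()
  add <- function(x) issues[[length(issues) + 1L]] <<- x
  n <- nrow(cohort)
  for (i in seq_len(n)) {
    r <- cohort[i, ]
    if (is.na(r$age) || r$age < 0) {
      add(issue(i, "age", "age must be a nonnegative integer"))
    }
    if (is.na(r$periods_last_12m) || r$periods_last_12m < 0) {
      add(issue(i, "periods_last_12m",
                "periods_last_12m must be a nonnegative integer"))
    }
    if (!r$regularity %in% regularity_levels()) {
      add(issue(i, "regularity",
                paste0("regularity must be one of: ",
                       paste(regularity_levels(), collapse = ", "))))
    }
    if (!r$oophorectomy %in% oophorectomy_levels()) {
      add(issue(i, "oophorectomy",
                paste0("oophorectomy must be one of: ",
                       paste(oophorectomy_levels(), collapse = ", "))))
    }
    if (identical(r$regularity, "stopped") &&
        !is.na(r$periods_last_12m) && r$periods_last_12m > 12) {
      add(issue(i, "periods_last_12m",
                "stopped menses is contradictory with more than 12 periods"))
    }
    for (fld in c("smoker_current", "exogenous_hormone_use", "pregnant",
                  "breastfeeding", "irregular_unrelated_to_menopause")) {
      if (is.na(r[[fld]])) {
        add(issue(i, fld, paste0(fld, " must be TRUE or FALSE")))
      }
    }
    if (!is.na(r$fsh) && r$fsh < 0) {
      add(issue(i, "fsh", "fsh must be nonnegative"))
    }
    if (!is.na(r$estradiol) && r$estradiol < 0) {
      add(issue(i, "estradiol", "estradiol must be nonnegative"))
    }
    if (xor(is.na(r$fsh), is.na(r$estradiol))) {
      add(issue(i, "fsh/estradiol",
                "hormone panel incomplete: both FSH and estradiol are needed; the pair is ignored in validation",
                advisory = TRUE))
    }
  }
  if (length(issues) == 0) {
    return(data.frame(row = integer(), field = character(),
                      message = character(), advisory = logical(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, issues)
}

#' Eligibility reasons per record
#'
#' @param cohort Cohort data frame.
#' @return List (one element per record) of character vectors of reason
#'   codes from [eligibility_reasons()]; empty vector means eligible.
#' @keywords internal
eligibility_reason_list <- function(cohort) {
  lapply(seq_len(nrow(cohort)), function(i) {
    r <- cohort[i, ]
    reasons <- character()
    if (isTRUE(r$exogenous_hormone_use)) reasons <- c(reasons, "HORMONE_USE")
    if (isTRUE(r$pregnant)) reasons <- c(reasons, "PREGNANT")
    if (isTRUE(r$breastfeeding)) reasons <- c(reasons, "BREASTFEEDING")
    if (isTRUE(r$irregular_unrelated_to_menopause)) {
      reasons <- c(reasons, "IRREGULAR_UNRELATED")
    }
    if (identical(r$oophorectomy, "bilateral")) {
      reasons <- c(reasons, "BILATERAL_OOPHORECTOMY")
    }
    reasons
  })
}

#' Apply the study eligibility filters
#'
#' Excludes women currently using exogenous sex hormones, pregnant or
#' breastfeeding women, women reporting irregular menstruation unrelated to
#' menopause, and women with bilateral oophorectomy (surgical menopause lies
#' outside the natural-transition model the score was developed on). Input
#' order is preserved and the filter is idempotent.
#'
#' @param cohort Cohort data frame.
#' @return A list with elements:
#'   \describe{
#'     \item{kept}{the eligible subset of `cohort`, original order;}
#'     \item{reports}{data frame with `id`, `eligible` and a list-column
#'       `reasons` of reason codes (empty iff eligible);}
#'     \item{exclusion_counts}{named integer vector, exclusions per reason.}
#'   }
#' @export
apply_eligibility_filters <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  reasons <- eligibility_reason_list(cohort)
  eligible <- vapply(reasons, function(x) length(x) == 0L, logical(1))
  counts <- vapply(eligibility_reasons(), function(code) {
    sum(vapply(reasons, function(x) code %in% x, logical(1)))
  }, integer(1))
  reports <- data.frame(id = cohort$id, eligible = eligible,
                        stringsAsFactors = FALSE)
  reports$reasons <- reasons
  list(kept = cohort[eligible, , drop = FALSE],
       reports = reports,
       exclusion_counts = counts)
}
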