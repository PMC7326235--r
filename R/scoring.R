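# Score assembly: age modifiers, fuzzy union, per-record and batch scoring.

#' Modified age under smoking and oophorectomy
#'
#' Adds the model's offsets to chronological age: nothing for nonsmokers
#' with two ovaries, +1 year after unilateral oophorectomy, +2 years for
#' current smokers, +3 years for smokers with one ovary (defaults).
#' Bilateral oophorectomy means surgical menopause, which the natural-
#' transition model does not cover; such records are ineligible and raise
#' an error here.
#'
#' @param age Age in years (vectorised).
#' @param smoker_current Logical (vectorised).
#' @param oophorectomy `"none"` or `"unilateral"` (vectorised);
#'   `"bilateral"` errors.
#' @param model A `ras_model` providing the offsets; if its
#'   `use_modifiers` is `FALSE` the age is returned unchanged.
#' @return Modified age in years.
#' @examples
#' modified_age(50, FALSE, "none")        # 50
#' modified_age(50, TRUE, "unilateral")   # 53
#' @export
modified_age <- function(age, smoker_current, oophorectomy,
                         model = default_ras_model()) {
  stopifnot(inherits(model, "ras_model"))
  if (any(oophorectomy == "bilateral")) {
    stop("bilateral oophorectomy: record is ineligible for scoring ",
         "(surgical menopause, outside model support)")
  }
  if (!all(oophorectomy %in% c("none", "unilateral"))) {
    stop("oophorectomy must be 'none' or 'unilateral'")
  }
  if (!model$use_modifiers) return(age)
  age + model$smoking_offset * as.numeric(smoker_current) +
    model$unilateral_oophorectomy_offset * (oophorectomy == "unilateral")
}

#' Algebraic fuzzy union of two membership values
#'
#' The probabilistic-sum union `a + b - a*b`: the two degrees of belonging
#' are added and their overlap subtracted. Commutative, with 0 as neutral
#' and 1 as absorbing element; the result stays in \[0, 1\]. Inputs outside
#' \[0, 1\] are an error — clamping is the membership evaluators' job, not
#' the aggregator's.
#'
#' @param a,b Membership values in \[0, 1\] (vectorised).
#' @return The union membership.
#' @export
fuzzy_union <- function(a, b) {
  if (any(is.na(a)) || any(is.na(b)) ||
      any(a < 0 | a > 1) || any(b < 0 | b > 1)) {
    stop("fuzzy_union inputs must lie in [0, 1]")
  }
  a + b - a * b
}

#' Reproductive ageing score for given period count and age
#'
#' The score is the fuzzy union of the period-count membership mu_A and
#' the age membership mu_B evaluated at the modified age:
#' `RAS = mu_A + mu_B - mu_A * mu_B`, a number between 0.00
#' (nonmenopausal) and 1.00 (postmenopausal).
#'
#' @param period Periods in the last twelve months (vectorised).
#' @param age Age in years (vectorised).
#' @param smoker_current,oophorectomy Modifier inputs, see
#'   [modified_age()].
#' @param model A `ras_model`.
#' @return Score values in \[0, 1\].
#' @examples
#' ras_score(period = 0, age = 66)   # ~1.00, postmenopausal
#' ras_score(period = 12, age = 50)  # ~0.44, driven by age alone
#' @export
ras_score <- function(period, age, smoker_current = FALSE,
                      oophorectomy = "none",
                      model = default_ras_model()) {
  m_age <- modified_age(age, smoker_current, oophorectomy, model)
  fuzzy_union(eval_mu_a(period, model$mu_a), eval_mu_b(m_age, model$mu_b))
}

#' Score a cohort of questionnaire records
#'
#' Applies the eligibility filters and scores every eligible record,
#' reporting all intermediate values. Ineligible records are not dropped:
#' they keep their position with a missing score and the exclusion reason,
#' so batches never abort on a single ineligible woman. Scoring a batch
#' twice gives identical output.
#'
#' @param cohort Cohort data frame.
#' @param model A `ras_model`.
#' @param digits Optional presentation rounding of the score (e.g. 2 for
#'   the conventional two-decimal display); `NULL` (default) reports full
#'   floating precision. Rounding is presentation-only and never feeds
#'   back into the computation.
#' @return Data frame with columns `id`, `ras`, `mu_a`, `mu_b`, `m_age`,
#'   `excluded_reason` (empty string for scored records), in input order.
#' @export
score_cohort <- function(cohort, model = default_ras_model(),
                         digits = NULL) {
  stopifnot(is.data.frame(cohort), inherits(model, "ras_model"))
  reasons <- eligibility_reason_list(cohort)
  eligible <- vapply(reasons, function(x) length(x) == 0L, logical(1))
  out <- data.frame(id = cohort$id,
                    ras = NA_real_, mu_a = NA_real_, mu_b = NA_real_,
                    m_age = NA_real_,
                    excluded_reason = vapply(reasons, paste,
                                             character(1), collapse = ";"),
                    stringsAsFactors = FALSE)
  if (any(eligible)) {
    el <- cohort[eligible, , drop = FALSE]
    m_age <- modified_age(el$age, el$smoker_current, el$oophorectomy, model)
    a <- eval_mu_a(el$periods_last_12m, model$mu_a)
    b <- eval_mu_b(m_age, model$mu_b)
    out$ras[eligible] <- fuzzy_union(a, b)
    out$mu_a[eligible] <- a
    out$mu_b[eligible] <- b
    out$m_age[eligible] <- m_age
  }
  if (!is.null(digits)) out$ras <- round(out$ras, digits)
  out
}
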