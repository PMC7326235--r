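# Hormone-based validation: FSH/estradiol cut-off classification, ROC
# analysis of the score, and quartile summaries.

#' Serum hormone cut-offs defining the menopausal classes
#'
#' The established combined cut-offs: nonmenopausal means FSH <= 20 IU/L
#' together with 17beta-estradiol >= 147 pmol/L; postmenopausal means
#' FSH >= 80 IU/L together with estradiol <= 73 pmol/L. Women satisfying
#' neither rule are classed perimenopausal.
#'
#' @param fsh_nonmeno_max Upper FSH bound for the nonmenopausal rule, IU/L.
#' @param e2_nonmeno_min Lower estradiol bound for the nonmenopausal rule,
#'   pmol/L.
#' @param fsh_postmeno_min Lower FSH bound for the postmenopausal rule,
#'   IU/L.
#' @param e2_postmeno_max Upper estradiol bound for the postmenopausal
#'   rule, pmol/L.
#' @return An object of class `hormone_cutoffs`.
#' @export
hormone_cutoffs <- function(fsh_nonmeno_max = 20, e2_nonmeno_min = 147,
                            fsh_postmeno_min = 80, e2_postmeno_max = 73) {
  stopifnot(fsh_nonmeno_max < fsh_postmeno_min,
            e2_postmeno_max < e2_nonmeno_min,
            fsh_nonmeno_max > 0, e2_postmeno_max > 0)
  structure(list(fsh_nonmeno_max = fsh_nonmeno_max,
                 e2_nonmeno_min = e2_nonmeno_min,
                 fsh_postmeno_min = fsh_postmeno_min,
                 e2_postmeno_max = e2_postmeno_max),
            class = "hormone_cutoffs")
}

#' Menopausal class labels
#'
#' @return Character vector: nonmenopausal, perimenopausal, postmenopausal.
#' @export
menopausal_classes <- function() {
  c("nonmenopausal", "perimenopausal", "postmenopausal")
}

#' Classify women by hormone cut-offs
#'
#' @param fsh FSH in IU/L (vectorised, nonnegative, no missing values —
#'   callers skip records without a complete panel).
#' @param estradiol 17beta-estradiol in pmol/L (vectorised, nonnegative).
#' @param cutoffs A `hormone_cutoffs`.
#' @return Factor with levels [menopausal_classes()].
#' @examples
#' classify_menopausal_status(11, 264)   # nonmenopausal
#' classify_menopausal_status(124, 12)   # postmenopausal
#' @export
classify_menopausal_status <- function(fsh, estradiol,
                                       cutoffs = hormone_cutoffs()) {
  stopifnot(inherits(cutoffs, "hormone_cutoffs"))
  if (any(is.na(fsh)) || any(is.na(estradiol))) {
    stop("hormone values must be present; skip records with missing panels")
  }
  if (any(fsh < 0) || any(estradiol < 0)) {
    stop("hormone values must be nonnegative")
  }
  cls <- rep("perimenopausal", length(fsh))
  cls[fsh <= cutoffs$fsh_nonmeno_max &
        estradiol >= cutoffs$e2_nonmeno_min] <- "nonmenopausal"
  cls[fsh >= cutoffs$fsh_postmeno_min &
        estradiol <= cutoffs$e2_postmeno_max] <- "postmenopausal"
  factor(cls, levels = menopausal_classes())
}

#' ROC curve and AUC of a score against binary labels
#'
#' Computes the ROC curve of `scores` for separating positives from
#' negatives, the area under it, and a 95% DeLong confidence interval.
#' Higher scores are taken to indicate the positive class; the AUC equals
#' the Mann-Whitney pair statistic P(score_pos > score_neg) + 0.5 P(tie).
#'
#' @param scores Numeric score per subject.
#' @param positive Logical label per subject; at least one `TRUE` and one
#'   `FALSE` are required.
#' @return A list of class `ras_roc`: `points` (data frame of `fpr`, `tpr`
#'   from (0,0) to (1,1)), `auc`, `ci_low`, `ci_high`, `ci_method`,
#'   `n_positive`, `n_negative`.
#' @export
ras_roc <- function(scores, positive) {
  stopifnot(length(scores) == length(positive))
  positive <- as.logical(positive)
  if (any(is.na(scores)) || any(is.na(positive))) {
    stop("scores and labels must be non-missing")
  }
  if (!any(positive) || all(positive)) {
    stop("labels are degenerate: need at least one positive and one negative")
  }
  r <- pROC::roc(response = positive, predictor = scores,
                 levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  # at AUC exactly 0 or 1 the DeLong variance degenerates and pROC notes
  # the interval is trivial; that is expected, not actionable
  ci <- suppressWarnings(pROC::ci.auc(r, method = "delong"))
  pts <- data.frame(fpr = 1 - r$specificities, tpr = r$sensitivities)
  pts <- pts[order(pts$fpr, pts$tpr), , drop = FALSE]
  rownames(pts) <- NULL
  structure(list(points = pts,
                 auc = as.numeric(pROC::auc(r)),
                 ci_low = as.numeric(ci[1]), ci_high = as.numeric(ci[3]),
                 ci_method = "DeLong",
                 n_positive = sum(positive),
                 n_negative = sum(!positive)),
            class = "ras_roc")
}

#' @export
print.ras_roc <- function(x, ...) {
  cat(sprintf("ROC: AUC %.3f (95%% CI %.3f-%.3f, %s), %d positives / %d negatives\n",
              x$auc, x$ci_low, x$ci_high, x$ci_method,
              x$n_positive, x$n_negative))
  invisible(x)
}

#' Validate scores against hormone-defined menopausal classes
#'
#' Runs the two validation contrasts: (1) nonmenopausal women versus the
#' remaining peri- and postmenopausal women, and (2) postmenopausal women
#' versus the remaining non- and perimenopausal women, with the score as
#' the discriminator in both. Records without a complete hormone panel are
#' dropped with a logged count, never imputed.
#'
#' @param scored Data frame with columns `ras`, `fsh`, `estradiol` (e.g. a
#'   [score_cohort()] result merged back with the cohort's hormone
#'   columns, or a cohort with a `ras` column added).
#' @param cutoffs A `hormone_cutoffs`.
#' @return List with elements `nonmeno_vs_rest` and `post_vs_rest` (both
#'   `ras_roc`), `class_counts`, `n_used`, `n_dropped`.
#' @export
validate_against_hormones <- function(scored, cutoffs = hormone_cutoffs()) {
  stopifnot(is.data.frame(scored),
            all(c("ras", "fsh", "estradiol") %in% names(scored)))
  complete <- !is.na(scored$ras) & !is.na(scored$fsh) &
    !is.na(scored$estradiol)
  n_dropped <- sum(!complete)
  if (n_dropped > 0) {
    message(n_dropped,
            " record(s) without score or complete hormone panel dropped")
  }
  s <- scored[complete, , drop = FALSE]
  if (nrow(s) < 2) stop("fewer than 2 records with complete data")
  cls <- classify_menopausal_status(s$fsh, s$estradiol, cutoffs)
  if (length(unique(cls)) < 2) {
    stop("fewer than 2 menopausal classes present; contrasts are undefined")
  }
  list(
    nonmeno_vs_rest = ras_roc(s$ras, cls != "nonmenopausal"),
    post_vs_rest = ras_roc(s$ras, cls == "postmenopausal"),
    class_counts = table(cls),
    n_used = nrow(s),
    n_dropped = n_dropped
  )
}

#' Score-quartile summary of reproductive characteristics
#'
#' Summarises age, menstrual pattern and hormone levels within the four
#' conventional score bins 0.00-0.25, 0.26-0.50, 0.51-0.75 and 0.76-1.00.
#' Binning applies to the score rounded to two decimals (matching the
#' two-decimal bin labels), with bins closed on the right at 0.25, 0.50
#' and 0.75.
#'
#' @param cohort Cohort data frame.
#' @param scores A [score_cohort()] result for the same cohort; computed
#'   with the default model when omitted. Unscored (ineligible) records
#'   are left out.
#' @return Data frame, one row per populated-or-not bin: `bin`, `n`, mean
#'   and SD of age and of period count, percentages with regular menses,
#'   irregular menses and amenorrhea (stopped), and median/IQR bounds of
#'   FSH and estradiol (NA when no hormone panels are present in a bin).
#' @export
quartile_summary <- function(cohort, scores = score_cohort(cohort)) {
  stopifnot(is.data.frame(cohort), is.data.frame(scores),
            nrow(cohort) == nrow(scores),
            all(cohort$id == scores$id))
  keep <- !is.na(scores$ras)
  if (!any(keep)) stop("no scored records to summarise")
  dat <- cohort[keep, , drop = FALSE]
  ras2 <- round(scores$ras[keep], 2)
  labels <- c("0.00-0.25", "0.26-0.50", "0.51-0.75", "0.76-1.00")
  bin <- cut(ras2, breaks = c(-Inf, 0.25, 0.50, 0.75, Inf),
             labels = labels, right = TRUE)
  q <- function(x, p) if (all(is.na(x))) NA_real_ else
    as.numeric(stats::quantile(x, p, na.rm = TRUE))
  rows <- lapply(labels, function(lb) {
    d <- dat[bin == lb, , drop = FALSE]
    n <- nrow(d)
    pct <- function(lvl) if (n == 0) NA_real_ else
      100 * mean(d$regularity == lvl)
    data.frame(
      bin = lb, n = n,
      age_mean = if (n) mean(d$age) else NA_real_,
      age_sd = if (n > 1) stats::sd(d$age) else NA_real_,
      periods_mean = if (n) mean(d$periods_last_12m) else NA_real_,
      periods_sd = if (n > 1) stats::sd(d$periods_last_12m) else NA_real_,
      pct_regular = pct("regular"),
      pct_irregular = pct("irregular"),
      pct_amenorrhea = pct("stopped"),
      fsh_median = q(d$fsh, 0.5), fsh_q1 = q(d$fsh, 0.25),
      fsh_q3 = q(d$fsh, 0.75),
      e2_median = q(d$estradiol, 0.5), e2_q1 = q(d$estradiol, 0.25),
      e2_q3 = q(d$estradiol, 0.75),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
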