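# Shared test helpers: record construction and an independent AUC oracle.

make_record <- function(id = "w1", age = 50, periods = 12,
                        regularity = "regular", smoker = FALSE,
                        oophorectomy = "none", hormones = FALSE,
                        pregnant = FALSE, breastfeeding = FALSE,
                        exo_hormones = FALSE, irregular_unrelated = FALSE,
                        fsh = NA_real_, estradiol = NA_real_) {
  if (hormones && is.na(fsh)) { fsh <- 11; estradiol <- 264 }
  participant_record(
    id = id, age = age, periods_last_12m = periods,
    regularity = regularity, smoker_current = smoker,
    oophorectomy = oophorectomy, exogenous_hormone_use = exo_hormones,
    pregnant = pregnant, breastfeeding = breastfeeding,
    irregular_unrelated_to_menopause = irregular_unrelated,
    fsh = fsh, estradiol = estradiol
  )
}

make_cohort <- function(...) {
  do.call(rbind, list(...))
}

# Brute-force Mann-Whitney pair counting: P(pos > neg) + 0.5 P(tie).
# Deliberately quadratic and independent of the package's ROC path.
auc_bruteforce <- function(scores, positive) {
  p <- scores[positive]
  n <- scores[!positive]
  cmp <- outer(p, n, ">") + 0.5 * outer(p, n, "==")
  mean(cmp)
}

# Hand-built proportion series on a known grid, for fit recovery tests.
make_series <- function(grid_value, proportion, grid) {
  structure(data.frame(grid_value = grid_value, proportion = proportion),
            grid = grid, class = c("ras_proportions", "data.frame"))
}
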