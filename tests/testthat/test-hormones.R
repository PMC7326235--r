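test_that("hormone classification follows the combined cut-off rules", {
  expect_identical(as.character(classify_menopausal_status(11, 264)),
                   "nonmenopausal")
  expect_identical(as.character(classify_menopausal_status(124, 12)),
                   "postmenopausal")
  expect_identical(as.character(classify_menopausal_status(50, 100)),
                   "perimenopausal")
  # boundary values belong to the extreme classes (<=, >= rules)
  expect_identical(as.character(classify_menopausal_status(20, 147)),
                   "nonmenopausal")
  expect_identical(as.character(classify_menopausal_status(80, 73)),
                   "postmenopausal")
  expect_error(classify_menopausal_status(NA, 100), "present")
  expect_error(classify_menopausal_status(10, -1), "nonnegative")
  expect_error(hormone_cutoffs(fsh_nonmeno_max = 90), "fsh")
})

test_that("ROC handles perfect separation, inversion and ties", {
  perfect <- ras_roc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))
  expect_identical(perfect$auc, 1)
  inverted <- ras_roc(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(inverted$auc, 0)
  tied <- ras_roc(c(1, 2, 2, 3), c(FALSE, TRUE, FALSE, TRUE))
  expect_identical(tied$auc, 0.875)
  expect_error(ras_roc(c(1, 2), c(TRUE, TRUE)), "degenerate")
})

test_that("ROC curve points run monotonically from (0,0) to (1,1) and CI brackets AUC", {
  set.seed(99)
  r <- ras_roc(rnorm(60), rep(c(TRUE, FALSE), 30))
  pts <- r$points
  expect_equal(unlist(pts[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(pts[nrow(pts), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(pts$fpr) >= 0))
  expect_true(all(diff(pts$tpr) >= 0))
  expect_lte(r$ci_low, r$auc)
  expect_gte(r$ci_high, r$auc)
  expect_identical(r$ci_method, "DeLong")
})

test_that("AUC equals brute-force pair counting and is antisymmetric", {
  set.seed(7)
  for (i in 1:25) {
    n <- sample(4:50, 1)
    scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(labels) || all(labels)) next
    r <- ras_roc(scores, labels)
    expect_equal(r$auc, auc_bruteforce(scores, labels), tolerance = 1e-12)
    # swapping the class roles, or negating the scores, complements the AUC
    expect_equal(ras_roc(scores, !labels)$auc, 1 - r$auc, tolerance = 1e-12)
    expect_equal(ras_roc(-scores, labels)$auc, 1 - r$auc, tolerance = 1e-12)
  }
})

test_that("hormone validation runs both contrasts and rejects one-class data", {
  cfg <- synthetic_cohort_config(n = 1500, seed = 21)
  cohort <- generate_cohort(cfg)
  scores <- score_cohort(cohort)
  merged <- cbind(scores, cohort[, c("fsh", "estradiol")])
  v <- suppressMessages(validate_against_hormones(merged))
  expect_s3_class(v$nonmeno_vs_rest, "ras_roc")
  expect_s3_class(v$post_vs_rest, "ras_roc")
  expect_identical(v$n_used + v$n_dropped, nrow(cohort))
  expect_gt(v$nonmeno_vs_rest$auc, 0.5)

  all_non <- data.frame(ras = runif(20), fsh = rep(5, 20),
                        estradiol = rep(300, 20))
  expect_error(validate_against_hormones(all_non), "classes")
})

test_that("quartile summary bins on the rounded score with right-closed bounds", {
  cohort <- make_cohort(
    make_record("a", age = 42, periods = 12),
    make_record("b", age = 47, periods = 12),
    make_record("c", age = 50, periods = 8, regularity = "irregular"),
    make_record("d", age = 60, periods = 0, regularity = "stopped",
                fsh = 124, estradiol = 12)
  )
  scores <- score_cohort(cohort)
  scores$ras <- c(0.10, 0.30, 0.60, 0.90)
  qs <- quartile_summary(cohort, scores)
  expect_identical(qs$n, rep(1L, 4))
  expect_identical(sum(qs$n), nrow(cohort))
  expect_equal(qs$fsh_median[4], 124)

  # a score of 0.254 displays as 0.25 and stays in the first bin
  one <- score_cohort(make_record("z", age = 40))
  one$ras <- 0.254
  qz <- quartile_summary(make_record("z", age = 40), one)
  expect_identical(qz$n[1], 1L)
  expect_identical(sum(qz$n), 1L)

  # percentages in a populated bin sum to 100
  row_pcts <- qs$pct_regular + qs$pct_irregular + qs$pct_amenorrhea
  expect_equal(row_pcts, rep(100, 4))
})
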