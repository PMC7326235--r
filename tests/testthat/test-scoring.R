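test_that("the age modifier table holds for all four cases", {
  expect_identical(modified_age(50, FALSE, "none"), 50)
  expect_identical(modified_age(50, FALSE, "unilateral"), 51)
  expect_identical(modified_age(50, TRUE, "none"), 52)
  expect_identical(modified_age(50, TRUE, "unilateral"), 53)
  expect_error(modified_age(50, FALSE, "bilateral"), "ineligible")
})

test_that("modifiers can be disabled through the model", {
  off <- ras_model(use_modifiers = FALSE)
  expect_identical(modified_age(50, TRUE, "unilateral", off), 50)
  expect_identical(ras_score(12, 50, smoker_current = TRUE, model = off),
                   ras_score(12, 50))
})

test_that("fuzzy union identities hold exactly and bad inputs error", {
  expect_identical(fuzzy_union(0, 0.5), 0.5)
  expect_identical(fuzzy_union(1, 0.3), 1)
  expect_identical(fuzzy_union(0.5, 0.5), 0.75)
  for (i in 1:20) {
    a <- i / 21
    b <- (21 - i) / 23
    expect_identical(fuzzy_union(a, b), fuzzy_union(b, a))
    expect_gte(fuzzy_union(a, b), max(a, b))
  }
  expect_error(fuzzy_union(-0.1, 0.5), "\\[0, 1\\]")
  expect_error(fuzzy_union(0.5, 1.2), "\\[0, 1\\]")
})

test_that("scores match the published model at reference inputs", {
  # amenorrheic 66-year-old: both memberships near 1
  expect_equal(ras_score(0, 66), 0.9999257, tolerance = 1e-5)
  # regularly menstruating 50-year-old: mu_A clamps to 0, age term drives
  expect_equal(ras_score(12, 50), 0.4437393, tolerance = 1e-5)
  # a model that is zero everywhere scores (essentially) zero
  null_model <- ras_model(mu_a = mu_a_params(0, 0, 0, 0, 0),
                          mu_b = mu_b_params(0, 0, -50))
  expect_lt(ras_score(12, 50, model = null_model), 1e-15)
})

test_that("batch scoring preserves order, reports exclusions, and is deterministic", {
  cohort <- make_cohort(
    make_record("a", age = 45, periods = 12),
    make_record("b", age = 52, periods = 3, regularity = "irregular"),
    make_record("c", age = 50, pregnant = TRUE),
    make_record("d", age = 60, periods = 0, regularity = "stopped")
  )
  s1 <- score_cohort(cohort)
  expect_identical(s1$id, cohort$id)
  expect_true(is.na(s1$ras[3]))
  expect_identical(s1$excluded_reason[3], "PREGNANT")
  expect_identical(s1$excluded_reason[c(1, 2, 4)], rep("", 3))
  expect_false(anyNA(s1$ras[c(1, 2, 4)]))
  expect_identical(score_cohort(cohort), s1)
  # two-decimal display rounding is presentation-only
  s2 <- score_cohort(cohort, digits = 2)
  expect_identical(s2$ras, round(s1$ras, 2))
  expect_identical(s2$mu_b, s1$mu_b)
})

test_that("scores stay in [0,1] and increase with age and with modifiers", {
  grid <- expand.grid(period = 0:15, age = 38:66)
  s <- ras_score(grid$period, grid$age)
  expect_true(all(s >= 0 & s <= 1))
  a <- eval_mu_a(grid$period)
  b <- eval_mu_b(grid$age)
  expect_true(all(s >= pmax(a, b) - 1e-12))
  for (p in c(0L, 6L, 12L, 15L)) {
    expect_true(all(diff(ras_score(rep(p, 29), 38:66)) >= 0))
  }
  base <- ras_score(grid$period, grid$age)
  smoke <- ras_score(grid$period, grid$age, smoker_current = TRUE)
  unilat <- ras_score(grid$period, grid$age, oophorectomy = "unilateral")
  expect_true(all(smoke >= base))
  expect_true(all(unilat >= base))
})
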