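test_that("crosstabs count each record into exactly one cell", {
  cohort <- do.call(rbind, lapply(1:5, function(i) {
    make_record(paste0("w", i), age = 45, periods = 12,
                regularity = "regular")
  }))
  tab <- build_period_crosstab(cohort)
  expect_identical(nrow(tab), 1L)
  expect_identical(tab$grid_value, 12L)
  expect_identical(tab$n_regular, 5L)
  expect_identical(tab$n_irregular + tab$n_stopped, 0L)

  ages <- make_cohort(
    make_record("a", age = 50, regularity = "stopped", periods = 0),
    make_record("b", age = 50, regularity = "stopped", periods = 0),
    make_record("c", age = 50, regularity = "stopped", periods = 0)
  )
  atab <- build_age_crosstab(ages)
  expect_identical(atab$grid_value, 50L)
  expect_identical(atab$n_stopped, 3L)

  empty <- build_period_crosstab(make_record("x")[0, ])
  expect_identical(nrow(empty), 0L)
})

test_that("grand total equals the number of records and order is irrelevant", {
  cohort <- generate_cohort(synthetic_cohort_config(n = 400, seed = 3))
  tab <- build_period_crosstab(cohort)
  expect_identical(crosstab_total(tab), nrow(cohort))
  shuffled <- cohort[rev(seq_len(nrow(cohort))), ]
  expect_equal(build_period_crosstab(shuffled), tab, ignore_attr = FALSE)
  expect_equal(build_age_crosstab(shuffled), build_age_crosstab(cohort))
})

test_that("proportion series follow x/(x+y+z) and z/(x+y+z)", {
  tab <- structure(data.frame(grid_value = c(11L, 12L),
                              n_regular = c(66L, 779L),
                              n_irregular = c(22L, 31L),
                              n_stopped = c(1L, 1L)),
                   grid = "periods",
                   class = c("ras_crosstab", "data.frame"))
  p <- proportion_regular(tab)
  expect_equal(round(p$proportion, 3), c(0.742, 0.961))

  zero <- structure(data.frame(grid_value = 5L, n_regular = 0L,
                               n_irregular = 0L, n_stopped = 10L),
                    grid = "periods",
                    class = c("ras_crosstab", "data.frame"))
  expect_equal(proportion_regular(zero)$proportion, 0)
  expect_equal(proportion_stopped(
    structure(zero, grid = "age")
  )$proportion, 1)
})

test_that("zero-total grid rows are dropped with a warning", {
  tab <- structure(data.frame(grid_value = c(1L, 2L),
                              n_regular = c(3L, 0L),
                              n_irregular = c(1L, 0L),
                              n_stopped = c(0L, 0L)),
                   grid = "periods",
                   class = c("ras_crosstab", "data.frame"))
  expect_warning(p <- proportion_regular(tab), "zero total")
  expect_identical(p$grid_value, 1L)
})

test_that("crosstab CSV round-trips and rejects malformed files", {
  tab <- build_age_crosstab(generate_cohort(
    synthetic_cohort_config(n = 300, seed = 5)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_crosstab_csv(tab, path)
  back <- read_crosstab_csv(path, grid = "age")
  expect_equal(as.data.frame(back), as.data.frame(tab))

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("grid_value,n_regular,n_irregular,n_stopped",
               "1,-2,0,0"), bad)
  expect_error(read_crosstab_csv(bad), "nonnegative")
})

test_that("packaged development crosstabs load with the documented totals", {
  pt <- rhine_period_crosstab()
  at <- rhine_age_crosstab()
  expect_identical(crosstab_total(pt), 3107L)
  expect_identical(crosstab_total(at), 3107L)
  expect_identical(range(pt$grid_value), c(0L, 15L))
  expect_identical(range(at$grid_value), c(38L, 66L))
})
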