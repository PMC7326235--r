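test_that("period membership matches hand-computed values of the published curve", {
  # u = period - 0.7 with the published quartic exponent
  expect_equal(eval_mu_a(0), 0.9088677, tolerance = 1e-6)
  # at 12 periods the exponential overshoots 1 and the raw value clamps to 0
  expect_identical(eval_mu_a(12), 0)
  expect_gt(exp(-0.00047 * 11.3^4 + 0.009 * 11.3^3 - 0.0307 * 11.3^2 +
                  0.086 * 11.3 - 2.317), 1)
  # all-zero coefficients: exp(0) = 1, membership identically 0
  flat <- mu_a_params(0, 0, 0, 0, 0)
  expect_identical(eval_mu_a(0:15, flat), rep(0, 16))
})

test_that("period counts above 15 are clamped to 15 with a warning", {
  expect_warning(v <- eval_mu_a(20), "clamped")
  expect_identical(v, eval_mu_a(15))
  expect_error(eval_mu_a(-1), "nonnegative")
  expect_error(mu_a_params(NaN, 0, 0, 0, 0), "finite")
})

test_that("age membership is the quadratic logistic with no clamping needed", {
  expect_equal(eval_mu_b(50), 0.4437393, tolerance = 1e-6)
  flat <- mu_b_params(0, 0, 0)
  expect_identical(eval_mu_b(c(40, 50, 60), flat), rep(0.5, 3))
  expect_warning(hi <- eval_mu_b(200), "outside")
  expect_gt(hi, 0.999999)
  expect_error(mu_b_params(Inf, 0, 0), "finite")
})

test_that("memberships stay inside [0,1] and mu_B increases over the support", {
  periods <- 0:15
  ages <- 38:66
  a <- eval_mu_a(periods)
  b <- eval_mu_b(ages)
  expect_true(all(a >= 0 & a <= 1))
  expect_true(all(b > 0 & b < 1))
  expect_true(all(diff(b) > 0))
})

test_that("fitting recovers a curve that generated the series exactly", {
  gen_a <- mu_a_params(c4 = -0.0005, c3 = 0.009, c2 = -0.031,
                       c1 = 0.08, c0 = -2.4)
  grid <- 0:15
  p <- exp(gen_a$c4 * grid^4 + gen_a$c3 * grid^3 + gen_a$c2 * grid^2 +
             gen_a$c1 * grid + gen_a$c0)
  fit <- fit_mu_a(make_series(grid, p, "periods"))
  expect_true(fit$converged)
  expect_lt(fit$mse, 1e-12)
  refit_p <- 1 - eval_mu_a(grid, fit$params)
  expect_equal(refit_p, p, tolerance = 1e-6)

  gen_b <- mu_b_params(b2 = 0.005, b1 = -0.09, b0 = -8)
  ages <- 38:66
  pb <- plogis(gen_b$b2 * ages^2 + gen_b$b1 * ages + gen_b$b0)
  fitb <- fit_mu_b(make_series(ages, pb, "age"))
  expect_true(fitb$converged)
  expect_lt(fitb$mse, 1e-12)
  expect_equal(eval_mu_b(ages, fitb$params), pb, tolerance = 1e-6)
})

test_that("refits on the development series beat the published coefficients", {
  sp <- proportion_regular(rhine_period_crosstab())
  sa <- proportion_stopped(rhine_age_crosstab())
  fa <- fit_mu_a(sp)
  fb <- fit_mu_b(sa)
  expect_true(fa$converged)
  expect_true(fb$converged)
  expect_lte(fa$mse, membership_mse(default_mu_a(), sp))
  expect_lte(fb$mse, membership_mse(default_mu_b(), sa))
  # fitted proportion near 15 periods stays close to the observed 0.5
  fitted_15 <- 1 - eval_mu_a(15, fa$params)
  expect_lt(abs(fitted_15 - 0.5), 0.05)
  # the refitted age curve is still sigmoidal over the development ages
  b <- eval_mu_b(38:66, fb$params)
  expect_true(all(diff(b) >= 0))
})

test_that("fits demand a minimum number of grid points", {
  expect_error(fit_mu_a(make_series(0:4, rep(0.5, 5), "periods")),
               "at least 6")
  expect_error(fit_mu_b(make_series(40:42, rep(0.5, 3), "age")),
               "at least 4")
})
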