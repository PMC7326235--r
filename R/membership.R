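# Fuzzy membership functions: biquadratic exponential over period counts
# (mu_A) and quadratic logistic over modified age (mu_B), plus their
# nonlinear least-squares fitting from proportion series.

#' Parameters of the biquadratic exponential membership function
#'
#' mu_A models the degree of menstrual irregularity/amenorrhea from the
#' number of periods in the last year. With u = period - shift, the fitted
#' proportion of regular menstruators is
#' `exp(c4*u^4 + c3*u^3 + c2*u^2 + c1*u + c0)` and
#' `mu_A(period) = 1 - fitted_P(period)`, clamped into \[0, 1\].
#'
#' @param c4,c3,c2,c1,c0 Quartic polynomial coefficients of the exponent.
#' @param shift Offset subtracted from the period count before the
#'   polynomial is evaluated. The published curve uses 0.7; refits fix it
#'   at 0 since the quartic family is closed under shifts.
#' @return An object of class `mu_a_params`.
#' @export
mu_a_params <- function(c4, c3, c2, c1, c0, shift = 0) {
  p <- list(shift = shift, c4 = c4, c3 = c3, c2 = c2, c1 = c1, c0 = c0)
  if (!all(vapply(p, function(v) is.numeric(v) && length(v) == 1 &&
                    is.finite(v), logical(1)))) {
    stop("mu_A parameters must be finite numeric scalars")
  }
  structure(p, class = "mu_a_params")
}

#' Parameters of the quadratic logistic membership function
#'
#' mu_B models the degree of belonging to the postmenopausal state from
#' (modified) age: `mu_B(age) = plogis(b2*age^2 + b1*age + b0)`.
#'
#' @param b2,b1,b0 Coefficients of the quadratic linear predictor.
#' @return An object of class `mu_b_params`.
#' @export
mu_b_params <- function(b2, b1, b0) {
  p <- list(b2 = b2, b1 = b1, b0 = b0)
  if (!all(vapply(p, function(v) is.numeric(v) && length(v) == 1 &&
                    is.finite(v), logical(1)))) {
    stop("mu_B parameters must be finite numeric scalars")
  }
  structure(p, class = "mu_b_params")
}

#' Published default membership parameters
#'
#' The coefficients of the published curves developed on the RHINE
#' cross-tabulations: the biquadratic exponential with its 0.7 period
#' offset, and the quadratic logistic in age.
#'
#' @return `default_mu_a()` a `mu_a_params`; `default_mu_b()` a
#'   `mu_b_params`.
#' @export
default_mu_a <- function() {
  mu_a_params(c4 = -0.00047, c3 = 0.009, c2 = -0.0307, c1 = 0.086,
              c0 = -2.317, shift = 0.7)
}

#' @rdname default_mu_a
#' @export
default_mu_b <- function() {
  mu_b_params(b2 = 0.0047, b1 = -0.0866, b0 = -7.646)
}

# Fitted proportion of regular menstruators (the exponential itself,
# without the 1 - P flip or clamping).
fitted_p_period <- function(period, params) {
  u <- period - params$shift
  exp(params$c4 * u^4 + params$c3 * u^3 + params$c2 * u^2 +
        params$c1 * u + params$c0)
}

#' Evaluate the period-count membership function
#'
#' Returns `1 - exp(quartic(period - shift))` clamped into \[0, 1\]. The
#' published coefficients give a fitted proportion slightly above 1 around
#' 12-13 periods, so the raw membership dips marginally below 0 there;
#' clamping (applied after evaluation) is part of the model contract and
#' keeps the final score inside \[0.00, 1.00\]. Period counts above 15 are
#' clamped to 15 with a warning: the development data end at 15 periods and
#' the quartic is unconstrained beyond it.
#'
#' @param period Number of periods in the last twelve months (vectorised,
#'   each >= 0).
#' @param params A `mu_a_params`; defaults to the published coefficients.
#' @return Membership values in \[0, 1\].
#' @examples
#' eval_mu_a(0)   # ~0.909: no menses, high membership
#' eval_mu_a(12)  # 0: monthly menses, raw value clamped at 0
#' @export
eval_mu_a <- function(period, params = default_mu_a()) {
  stopifnot(inherits(params, "mu_a_params"))
  if (any(is.na(period)) || any(period < 0)) {
    stop("period must be nonnegative and non-missing")
  }
  if (any(period > 15)) {
    warning("period counts above 15 clamped to 15 (outside model support)")
    period <- pmin(period, 15)
  }
  pmin(pmax(1 - fitted_p_period(period, params), 0), 1)
}

#' Evaluate the age membership function
#'
#' The quadratic logistic `plogis(b2*age^2 + b1*age + b0)`, mathematically
#' already inside (0, 1). Ages outside the 35-70 year development support
#' draw a warning but are still evaluated.
#'
#' @param m_age Age in years, after any smoking/oophorectomy modification
#'   (vectorised, each >= 0).
#' @param params A `mu_b_params`; defaults to the published coefficients.
#' @return Membership values in (0, 1).
#' @examples
#' eval_mu_b(50)  # ~0.444
#' @export
eval_mu_b <- function(m_age, params = default_mu_b()) {
  stopifnot(inherits(params, "mu_b_params"))
  if (any(is.na(m_age)) || any(m_age < 0)) {
    stop("m_age must be nonnegative and non-missing")
  }
  if (any(m_age < 35 | m_age > 70)) {
    warning("age outside the 35-70 development range; value computed anyway")
  }
  stats::plogis(params$b2 * m_age^2 + params$b1 * m_age + params$b0)
}

new_fit_result <- function(params, mse, n_points, converged) {
  structure(list(params = params, mse = mse, n_points = n_points,
                 converged = converged),
            class = "ras_fit")
}

#' @export
print.ras_fit <- function(x, ...) {
  cat("Membership curve fit (", class(x$params)[1], ")\n", sep = "")
  cat("  points:", x$n_points, " converged:", x$converged,
      " MSE:", format(x$mse, digits = 4), "\n")
  invisible(x)
}

#' Fit the biquadratic exponential curve to a period proportion series
#'
#' Minimises the unweighted sum over grid points of
#' `(exp(quartic(period)) - P(period))^2` by Levenberg-Marquardt, started
#' from an ordinary linear least-squares fit of the quartic to `log(P)`
#' over points with P strictly inside (0, 1). The start and refinement are
#' deterministic; no random restarts. The shift is fixed at 0: a shifted
#' quartic is itself a quartic, so the offset is redundant in refits.
#'
#' @param series A `ras_proportions` over period counts, >= 6 grid points.
#' @return A `ras_fit` with the fitted `mu_a_params`, the achieved
#'   unweighted mean squared error, the number of grid points, and a
#'   convergence flag (non-convergence is reported, never silent).
#' @export
fit_mu_a <- function(series) {
  stopifnot(inherits(series, "ras_proportions"))
  g <- series$grid_value
  p <- series$proportion
  if (length(g) < 6) stop("fit_mu_a needs at least 6 grid points")
  inside <- p > 0 & p < 1
  if (sum(inside) < 5) stop("too few proportions strictly inside (0, 1)")
  X <- cbind(1, g, g^2, g^3, g^4)
  start <- stats::lm.fit(X[inside, , drop = FALSE], log(p[inside]))$coefficients
  resid_fn <- function(th) {
    exp(drop(X %*% th)) - p
  }
  fit <- minpack.lm::nls.lm(par = start, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(maxiter = 1000))
  params <- mu_a_params(c4 = fit$par[[5]], c3 = fit$par[[4]],
                        c2 = fit$par[[3]], c1 = fit$par[[2]],
                        c0 = fit$par[[1]], shift = 0)
  new_fit_result(params, mean(resid_fn(fit$par)^2), length(g),
                 converged = fit$info %in% 1:4)
}

#' Fit the quadratic logistic curve to an age proportion series
#'
#' Minimises the unweighted sum of `(plogis(quadratic(age)) - P(age))^2`
#' by Levenberg-Marquardt, started from a linear least-squares fit of the
#' quadratic to `qlogis(P)` with proportions clipped away from 0 and 1.
#'
#' @param series A `ras_proportions` over ages, >= 4 grid points.
#' @return A `ras_fit` with the fitted `mu_b_params`.
#' @export
fit_mu_b <- function(series) {
  stopifnot(inherits(series, "ras_proportions"))
  g <- series$grid_value
  p <- series$proportion
  if (length(g) < 4) stop("fit_mu_b needs at least 4 grid points")
  eps <- 1e-4
  pc <- pmin(pmax(p, eps), 1 - eps)
  X <- cbind(1, g, g^2)
  start <- stats::lm.fit(X, stats::qlogis(pc))$coefficients
  resid_fn <- function(th) {
    stats::plogis(drop(X %*% th)) - p
  }
  fit <- minpack.lm::nls.lm(par = start, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(maxiter = 1000))
  params <- mu_b_params(b2 = fit$par[[3]], b1 = fit$par[[2]],
                        b0 = fit$par[[1]])
  new_fit_result(params, mean(resid_fn(fit$par)^2), length(g),
                 converged = fit$info %in% 1:4)
}

#' Mean squared error of a membership parameter set against a series
#'
#' Evaluates the fitted proportion implied by `params` on the grid of
#' `series` and returns the unweighted mean of squared residuals. Useful to
#' compare a refit against the published coefficients on the same data.
#'
#' @param params A `mu_a_params` or `mu_b_params`.
#' @param series A `ras_proportions` on the matching grid.
#' @return Mean squared error (scalar).
#' @export
membership_mse <- function(params, series) {
  stopifnot(inherits(series, "ras_proportions"))
  fitted <- if (inherits(params, "mu_a_params")) {
    fitted_p_period(series$grid_value, params)
  } else if (inherits(params, "mu_b_params")) {
    stats::plogis(params$b2 * series$grid_value^2 +
                    params$b1 * series$grid_value + params$b0)
  } else {
    stop("params must be mu_a_params or mu_b_params")
  }
  mean((fitted - series$proportion)^2)
}
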