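# Seeded synthetic mid-life cohort generator. A latent reproductive-ageing
# stage per woman drives age-linked menstrual cessation, period counts,
# regularity and the FSH/estradiol panel, so fitting, scoring and hormone
# validation are all exercisable without external data.

#' Configuration of the synthetic cohort generator
#'
#' The generator draws, per woman, a latent transition stage
#' `u = plogis((age - stage_age_midpoint + noise) / stage_age_scale)` in
#' \[0, 1\] and from it the menstrual pattern and hormone panel. Defaults
#' emulate a mid-life European questionnaire cohort: ages uniform over
#' 38-66, transition midpoint 51 years (near the observed cessation
#' midpoint), and hormone medians anchored at typical nonmenopausal
#' (FSH 11 IU/L, estradiol 264 pmol/L) and postmenopausal
#' (FSH 124 IU/L, estradiol 12 pmol/L) values, interpolated log-linearly
#' in `u` with lognormal noise (FSH spreads are strongly right-skewed).
#' Exclusion flags default to small nonzero prevalences so the
#' eligibility filter is exercised.
#'
#' @param n Cohort size (>= 1).
#' @param seed Integer seed; same seed and config give an identical
#'   cohort.
#' @param age_range Integer ages sampled uniformly (inclusive bounds).
#' @param stage_age_midpoint,stage_age_scale Years; centre and steepness
#'   of the latent-stage logistic in age.
#' @param stage_noise_sd Years; between-woman jitter of the transition
#'   timing.
#' @param fsh_nonmeno_median,fsh_postmeno_median FSH medians (IU/L) at the
#'   two ends of the transition.
#' @param e2_nonmeno_median,e2_postmeno_median Estradiol medians (pmol/L)
#'   at the two ends.
#' @param hormone_sigma Standard deviation of the lognormal hormone noise
#'   (log scale).
#' @param hormone_use_rate,pregnancy_rate,breastfeeding_rate,irregular_unrelated_rate
#'   Prevalence of each exclusion flag.
#' @param smoking_prevalence Prevalence of current smoking.
#' @param unilateral_oophorectomy_rate,bilateral_oophorectomy_rate
#'   Prevalence of each oophorectomy status.
#' @return An object of class `synthetic_cohort_config`.
#' @export
synthetic_cohort_config <- function(n = 5000, seed = 1,
                                    age_range = c(38, 66),
                                    stage_age_midpoint = 51,
                                    stage_age_scale = 3,
                                    stage_noise_sd = 2,
                                    fsh_nonmeno_median = 11,
                                    fsh_postmeno_median = 124,
                                    e2_nonmeno_median = 264,
                                    e2_postmeno_median = 12,
                                    hormone_sigma = 0.5,
                                    hormone_use_rate = 0.05,
                                    pregnancy_rate = 0.01,
                                    breastfeeding_rate = 0.01,
                                    irregular_unrelated_rate = 0.02,
                                    smoking_prevalence = 0.2,
                                    unilateral_oophorectomy_rate = 0.03,
                                    bilateral_oophorectomy_rate = 0.01) {
  cfg <- list(n = n, seed = seed, age_range = age_range,
              stage_age_midpoint = stage_age_midpoint,
              stage_age_scale = stage_age_scale,
              stage_noise_sd = stage_noise_sd,
              fsh_nonmeno_median = fsh_nonmeno_median,
              fsh_postmeno_median = fsh_postmeno_median,
              e2_nonmeno_median = e2_nonmeno_median,
              e2_postmeno_median = e2_postmeno_median,
              hormone_sigma = hormone_sigma,
              hormone_use_rate = hormone_use_rate,
              pregnancy_rate = pregnancy_rate,
              breastfeeding_rate = breastfeeding_rate,
              irregular_unrelated_rate = irregular_unrelated_rate,
              smoking_prevalence = smoking_prevalence,
              unilateral_oophorectomy_rate = unilateral_oophorectomy_rate,
              bilateral_oophorectomy_rate = bilateral_oophorectomy_rate)
  check_num <- function(name, lo = 0, hi = Inf, len = 1) {
    v <- cfg[[name]]
    if (!is.numeric(v) || length(v) != len || any(!is.finite(v)) ||
        any(v < lo) || any(v > hi)) {
      stop("invalid config field: ", name)
    }
  }
  check_num("n", lo = 1)
  if (cfg$n != trunc(cfg$n)) stop("invalid config field: n")
  check_num("seed", lo = -2^31, hi = 2^31)
  check_num("age_range", lo = 0, len = 2)
  if (age_range[1] > age_range[2]) stop("invalid config field: age_range")
  check_num("stage_age_midpoint")
  check_num("stage_age_scale", lo = 1e-6)
  check_num("stage_noise_sd")
  for (f in c("fsh_nonmeno_median", "fsh_postmeno_median",
              "e2_nonmeno_median", "e2_postmeno_median")) {
    check_num(f, lo = 1e-6)
  }
  check_num("hormone_sigma")
  for (f in c("hormone_use_rate", "pregnancy_rate", "breastfeeding_rate",
              "irregular_unrelated_rate", "smoking_prevalence",
              "unilateral_oophorectomy_rate",
              "bilateral_oophorectomy_rate")) {
    check_num(f, lo = 0, hi = 1)
  }
  if (unilateral_oophorectomy_rate + bilateral_oophorectomy_rate > 1) {
    stop("invalid config field: unilateral_oophorectomy_rate")
  }
  structure(cfg, class = "synthetic_cohort_config")
}

#' Generate a synthetic questionnaire cohort
#'
#' Draws `config$n` participant records. The latent stage `u` determines:
#' menstrual cessation (probability `u`, making the stopped-by-age series
#' sigmoidal); among menstruating women, an irregularity probability and a
#' period count that slides from 12 toward 0 as `u` grows, with occasional
#' counts of 13-15 at intermediate stages (cycles both shorten and
#' lengthen early in the transition); and an FSH that rises and estradiol
#' that falls log-linearly in `u` between the configured medians. The
#' caller's RNG state is left untouched.
#'
#' @param config A [synthetic_cohort_config()].
#' @return Cohort data frame in the canonical schema, `config$n` rows.
#' @export
generate_cohort <- function(config = synthetic_cohort_config()) {
  stopifnot(inherits(config, "synthetic_cohort_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(config$seed)
  n <- config$n
  age <- sample(seq(config$age_range[1], config$age_range[2]), n,
                replace = TRUE)
  u <- stats::plogis((age - config$stage_age_midpoint +
                        stats::rnorm(n, 0, config$stage_noise_sd)) /
                       config$stage_age_scale)
  stopped <- stats::runif(n) < u
  periods <- integer(n)
  regularity <- character(n)

  # stopped women: usually 0 periods, occasionally a few residual ones
  ns <- sum(stopped)
  if (ns > 0) {
    periods[stopped] <- pmin(stats::rpois(ns, 0.2), 12L)
    regularity[stopped] <- "stopped"
  }
  # menstruating women: irregularity and period loss both scale with stage
  nm <- sum(!stopped)
  if (nm > 0) {
    um <- u[!stopped]
    irregular <- stats::runif(nm) < pmin(0.04 + 0.85 * um, 0.95)
    regularity[!stopped] <- ifelse(irregular, "irregular", "regular")
    p_drop <- ifelse(irregular, pmin(0.75 * um + 0.1, 0.95), 0.08 * um)
    periods[!stopped] <- 12L - stats::rbinom(nm, 12L, p_drop)
    # shortening cycles: 13-15 periods, most likely mid-transition
    extra <- stats::runif(nm) < 0.25 * 4 * um * (1 - um)
    periods[!stopped][extra] <- sample(13:15, sum(extra), replace = TRUE)
  }
  log_fsh <- log(config$fsh_nonmeno_median) +
    u * (log(config$fsh_postmeno_median) - log(config$fsh_nonmeno_median))
  log_e2 <- log(config$e2_nonmeno_median) +
    u * (log(config$e2_postmeno_median) - log(config$e2_nonmeno_median))
  fsh <- exp(log_fsh + stats::rnorm(n, 0, config$hormone_sigma))
  estradiol <- exp(log_e2 + stats::rnorm(n, 0, config$hormone_sigma))

  oo <- stats::runif(n)
  oophorectomy <- ifelse(oo < config$bilateral_oophorectomy_rate, "bilateral",
                  ifelse(oo < config$bilateral_oophorectomy_rate +
                           config$unilateral_oophorectomy_rate,
                         "unilateral", "none"))
  participant_record(
    id = sprintf("S%05d", seq_len(n)),
    age = age,
    periods_last_12m = periods,
    regularity = regularity,
    smoker_current = stats::runif(n) < config$smoking_prevalence,
    oophorectomy = oophorectomy,
    exogenous_hormone_use = stats::runif(n) < config$hormone_use_rate,
    pregnant = stats::runif(n) < config$pregnancy_rate,
    breastfeeding = stats::runif(n) < config$breastfeeding_rate,
    irregular_unrelated_to_menopause = stats::runif(n) <
      config$irregular_unrelated_rate,
    fsh = fsh,
    estradiol = estradiol
  )
}

#' Generate synthetic cross-tabulations
#'
#' Convenience wrapper for fit tests: generates a cohort, applies the
#' eligibility filters, and builds both cross-tabulations.
#'
#' @param config A [synthetic_cohort_config()].
#' @return List with elements `period_crosstab` and `age_crosstab`.
#' @export
generate_crosstab_fixture <- function(config = synthetic_cohort_config()) {
  cohort <- generate_cohort(config)
  kept <- apply_eligibility_filters(cohort)$kept
  list(period_crosstab = build_period_crosstab(kept),
       age_crosstab = build_age_crosstab(kept))
}
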