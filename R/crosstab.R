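# Cross-tabulations of menstrual regularity by period count and by age, and
# the proportion series the membership functions are fitted to.

new_crosstab <- function(df, grid) {
  df <- df[order(df$grid_value), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, grid = grid, class = c("ras_crosstab", "data.frame"))
}

crosstab_from_records <- function(records, key, grid) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0) {
    return(new_crosstab(data.frame(grid_value = integer(),
                                   n_regular = integer(),
                                   n_irregular = integer(),
                                   n_stopped = integer()), grid))
  }
  bad <- !records$regularity %in% regularity_levels()
  if (any(bad)) {
    stop("unrecognised regularity value in record(s): ",
         paste(which(bad), collapse = ", "))
  }
  tab <- table(factor(records[[key]]),
               factor(records$regularity, levels = regularity_levels()))
  df <- data.frame(
    grid_value = as.integer(rownames(tab)),
    n_regular = as.integer(tab[, "regular"]),
    n_irregular = as.integer(tab[, "irregular"]),
    n_stopped = as.integer(tab[, "stopped"])
  )
  new_crosstab(df, grid)
}

#' Cross-tabulate menstrual regularity by number of periods
#'
#' Counts, for each reported number of periods in the last twelve months,
#' how many women answered "regular", "irregular for a few months" and
#' "stopped". Each record increments exactly one cell, so the grand total
#' equals the number of records.
#'
#' @param records Cohort data frame, already filtered for eligibility.
#' @return A `ras_crosstab` data frame with columns `grid_value` (period
#'   count), `n_regular`, `n_irregular`, `n_stopped`.
#' @export
build_period_crosstab <- function(records) {
  crosstab_from_records(records, "periods_last_12m", "periods")
}

#' Cross-tabulate menstrual regularity by age
#'
#' As [build_period_crosstab()], keyed by whole year of age.
#'
#' @inheritParams build_period_crosstab
#' @return A `ras_crosstab` with `grid_value` holding age in years.
#' @export
build_age_crosstab <- function(records) {
  crosstab_from_records(records, "age", "age")
}

crosstab_grid <- function(tab) attr(tab, "grid", exact = TRUE)

#' Grand total of a cross-tabulation
#'
#' @param tab A `ras_crosstab`.
#' @return Total count over all cells.
#' @export
crosstab_total <- function(tab) {
  sum(tab$n_regular) + sum(tab$n_irregular) + sum(tab$n_stopped)
}

proportion_series <- function(tab, numerator) {
  stopifnot(inherits(tab, "ras_crosstab"))
  total <- tab$n_regular + tab$n_irregular + tab$n_stopped
  keep <- total > 0
  if (any(!keep)) {
    warning(sum(!keep), " grid row(s) with zero total dropped")
  }
  p <- numerator[keep] / total[keep]
  out <- data.frame(grid_value = tab$grid_value[keep], proportion = p)
  stopifnot(all(p >= 0 & p <= 1), !is.unsorted(out$grid_value, strictly = TRUE))
  structure(out, grid = crosstab_grid(tab),
            class = c("ras_proportions", "data.frame"))
}

#' Proportion of regularly menstruating women per period count
#'
#' For each period count the proportion P(period) = x / (x + y + z), where
#' x, y, z count the "regular", "irregular" and "stopped" answers. This is
#' the discrete series the biquadratic exponential membership curve
#' approximates (through its complement 1 - P).
#'
#' @param tab A period `ras_crosstab` from [build_period_crosstab()].
#' @return A `ras_proportions` data frame (`grid_value`, `proportion`);
#'   grid rows with zero total are dropped with a warning.
#' @export
proportion_regular <- function(tab) {
  proportion_series(tab, tab$n_regular)
}

#' Proportion of women with stopped menses per year of age
#'
#' For each age the proportion P(age) = z / (x + y + z) of women answering
#' that their periods have stopped. This sigmoidal series is what the
#' quadratic logistic membership curve approximates.
#'
#' @param tab An age `ras_crosstab` from [build_age_crosstab()].
#' @return A `ras_proportions` data frame.
#' @export
proportion_stopped <- function(tab) {
  proportion_series(tab, tab$n_stopped)
}

#' Read / write a cross-tabulation CSV
#'
#' The serialised form has columns `grid_value, n_regular, n_irregular,
#' n_stopped`; the packaged development cross-tabulations ship in this
#' format.
#'
#' @param path File path.
#' @param grid Grid semantics, `"periods"` or `"age"`.
#' @return For `read_crosstab_csv`, a `ras_crosstab`.
#' @export
read_crosstab_csv <- function(path, grid = c("periods", "age")) {
  grid <- match.arg(grid)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("grid_value", "n_regular", "n_irregular", "n_stopped")
  if (!identical(names(df), need)) {
    stop("crosstab CSV must have columns: ", paste(need, collapse = ", "))
  }
  counts <- as.matrix(df[, -1])
  if (any(is.na(counts)) || any(counts < 0) || any(counts != trunc(counts))) {
    stop("crosstab counts must be nonnegative integers")
  }
  new_crosstab(df, grid)
}

#' @rdname read_crosstab_csv
#' @param tab A `ras_crosstab` to serialise.
#' @export
write_crosstab_csv <- function(tab, path) {
  stopifnot(inherits(tab, "ras_crosstab"))
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Development cross-tabulations (RHINE questionnaire study)
#'
#' The two cross-tabulations of 3107 women aged 38-66 from the RHINE
#' multicentre questionnaire study on which the published membership curves
#' were developed: menstrual pattern by number of periods in the last year,
#' and presence of menstruations by age. These are packaged as plain-text
#' fixtures and are the canonical inputs for refitting the score's
#' membership functions.
#'
#' @return A `ras_crosstab` (period grid for `rhine_period_crosstab`, age
#'   grid for `rhine_age_crosstab`).
#' @export
rhine_period_crosstab <- function() {
  read_crosstab_csv(system.file("extdata", "rhine_period_crosstab.csv",
                                package = "rascore", mustWork = TRUE),
                    grid = "periods")
}

#' @rdname rhine_period_crosstab
#' @export
rhine_age_crosstab <- function() {
  read_crosstab_csv(system.file("extdata", "rhine_age_crosstab.csv",
                                package = "rascore", mustWork = TRUE),
                    grid = "age")
}
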