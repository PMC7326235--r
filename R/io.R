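# Cohort CSV readers/writers. One fixed dialect: UTF-8, comma delimiter,
# '.' decimal mark, booleans as 0/1, missing values as empty fields.

bool_cols <- function() {
  c("smoker_current", "exogenous_hormone_use", "pregnant", "breastfeeding",
    "irregular_unrelated_to_menopause")
}

#' Read a cohort CSV
#'
#' Expects a header row with the exact canonical columns (`id, age,
#' periods_last_12m, regularity, smoker_current, oophorectomy,
#' exogenous_hormone_use, pregnant, breastfeeding,
#' irregular_unrelated_to_menopause, fsh, estradiol`). Enum encodings:
#' `regularity` in regular/irregular/stopped, `oophorectomy` in
#' none/unilateral/bilateral; booleans 0/1; empty field = missing.
#' Malformed values raise an error naming the row and column.
#'
#' @param path File path.
#' @return Cohort data frame.
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", na.strings = NULL)
  if (!identical(names(df), cohort_columns())) {
    stop("cohort CSV must have exactly the columns: ",
         paste(cohort_columns(), collapse = ", "))
  }
  fail <- function(row, col, what) {
    stop(sprintf("cohort CSV %s: row %d, column %s: %s",
                 basename(path), row, col, what))
  }
  parse_int <- function(col) {
    v <- suppressWarnings(as.integer(df[[col]]))
    bad <- which(is.na(v) | df[[col]] == "")
    if (length(bad) > 0) fail(bad[1], col, "expected an integer")
    v
  }
  parse_bool <- function(col) {
    bad <- which(!df[[col]] %in% c("0", "1"))
    if (length(bad) > 0) fail(bad[1], col, "expected 0 or 1")
    df[[col]] == "1"
  }
  parse_enum <- function(col, levels) {
    bad <- which(!df[[col]] %in% levels)
    if (length(bad) > 0) {
      fail(bad[1], col,
           paste0("expected one of: ", paste(levels, collapse = ", ")))
    }
    df[[col]]
  }
  parse_opt_num <- function(col) {
    v <- rep(NA_real_, nrow(df))
    present <- df[[col]] != ""
    v[present] <- suppressWarnings(as.numeric(df[[col]][present]))
    bad <- which(present & is.na(v))
    if (length(bad) > 0) fail(bad[1], col, "expected a number or empty")
    v
  }
  out <- data.frame(id = df$id,
                    age = parse_int("age"),
                    periods_last_12m = parse_int("periods_last_12m"),
                    regularity = parse_enum("regularity", regularity_levels()),
                    stringsAsFactors = FALSE)
  out$smoker_current <- parse_bool("smoker_current")
  out$oophorectomy <- parse_enum("oophorectomy", oophorectomy_levels())
  for (col in setdiff(bool_cols(), "smoker_current")) {
    out[[col]] <- parse_bool(col)
  }
  out$fsh <- parse_opt_num("fsh")
  out$estradiol <- parse_opt_num("estradiol")
  out[, cohort_columns()]
}

#' Write a cohort CSV
#'
#' Inverse of [read_cohort_csv()]; write-then-read round-trips are
#' value-identical, with numeric fields at full precision.
#'
#' @param cohort Cohort data frame.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(is.data.frame(cohort),
            all(cohort_columns() %in% names(cohort)))
  out <- cohort[, cohort_columns()]
  for (col in bool_cols()) out[[col]] <- as.integer(out[[col]])
  for (col in c("fsh", "estradiol")) {
    v <- out[[col]]
    out[[col]] <- ifelse(is.na(v),
                         "",
                         format(v, digits = 17, scientific = FALSE,
                                trim = TRUE))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write a scoring result CSV
#'
#' @param scores A [score_cohort()] result.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_scores_csv <- function(scores, path) {
  utils::write.csv(scores, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
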