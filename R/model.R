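# The full score model: both membership parameter sets plus the age
# modifier offsets, with key-value text serialisation.

#' Assemble a reproductive ageing score model
#'
#' Bundles the two membership parameter sets with the age modifier offsets.
#' The modifiers add years to age before mu_B is evaluated: current smoking
#' and unilateral oophorectomy are both associated with earlier menopause,
#' so an affected woman of a given age sits further along the transition
#' than her unmodified age suggests. They can be disabled wholesale via
#' `use_modifiers` when smoking or oophorectomy are to be analysed
#' separately.
#'
#' @param mu_a A `mu_a_params` (default: published coefficients).
#' @param mu_b A `mu_b_params` (default: published coefficients).
#' @param smoking_offset Years added for current smokers (default 2, >= 0).
#' @param unilateral_oophorectomy_offset Years added after unilateral
#'   oophorectomy (default 1, >= 0).
#' @param use_modifiers Logical; `FALSE` scores on unmodified age.
#' @return An object of class `ras_model`.
#' @export
ras_model <- function(mu_a = default_mu_a(), mu_b = default_mu_b(),
                      smoking_offset = 2,
                      unilateral_oophorectomy_offset = 1,
                      use_modifiers = TRUE) {
  stopifnot(inherits(mu_a, "mu_a_params"), inherits(mu_b, "mu_b_params"),
            is.numeric(smoking_offset), smoking_offset >= 0,
            is.numeric(unilateral_oophorectomy_offset),
            unilateral_oophorectomy_offset >= 0,
            is.logical(use_modifiers), length(use_modifiers) == 1)
  structure(list(mu_a = mu_a, mu_b = mu_b,
                 smoking_offset = smoking_offset,
                 unilateral_oophorectomy_offset = unilateral_oophorectomy_offset,
                 use_modifiers = use_modifiers),
            class = "ras_model")
}

#' The published default score model
#'
#' The published membership coefficients with the standard modifier
#' offsets (+2 years current smoking, +1 year unilateral oophorectomy).
#'
#' @return A `ras_model`.
#' @export
default_ras_model <- function() ras_model()

#' @export
print.ras_model <- function(x, ...) {
  cat("Reproductive ageing score model\n")
  cat("  mu_A (period): shift=", x$mu_a$shift, ", exponent coefficients c4..c0: ",
      paste(format(unlist(x$mu_a[c("c4", "c3", "c2", "c1", "c0")])),
            collapse = ", "), "\n", sep = "")
  cat("  mu_B (age): b2=", format(x$mu_b$b2), ", b1=", format(x$mu_b$b1),
      ", b0=", format(x$mu_b$b0), "\n", sep = "")
  cat("  modifiers: ", if (x$use_modifiers) "on" else "off",
      " (smoking +", x$smoking_offset, "y, unilateral oophorectomy +",
      x$unilateral_oophorectomy_offset, "y)\n", sep = "")
  invisible(x)
}

model_fields <- function() {
  c("mu_a_shift", "mu_a_c4", "mu_a_c3", "mu_a_c2", "mu_a_c1", "mu_a_c0",
    "mu_b_b2", "mu_b_b1", "mu_b_b0",
    "smoking_offset", "unilateral_oophorectomy_offset", "use_modifiers")
}

#' Read / write a score model file
#'
#' Models serialise to a structured key-value text file (DCF), one field
#' per line, numeric values at full precision. Unknown keys are rejected
#' with the offending key named. The packaged default model file carries
#' the published coefficients.
#'
#' @param path File path.
#' @return For `read_ras_model`, a `ras_model`.
#' @export
read_ras_model <- function(path) {
  m <- read.dcf(path)
  if (nrow(m) != 1) stop("model file must contain exactly one record")
  keys <- colnames(m)
  unknown <- setdiff(keys, model_fields())
  if (length(unknown) > 0) {
    stop("unknown key(s) in model file: ", paste(unknown, collapse = ", "))
  }
  missing <- setdiff(model_fields(), keys)
  if (length(missing) > 0) {
    stop("model file is missing key(s): ", paste(missing, collapse = ", "))
  }
  num <- function(k) {
    v <- suppressWarnings(as.numeric(m[1, k]))
    if (is.na(v)) stop("model key ", k, " is not numeric")
    v
  }
  ras_model(
    mu_a = mu_a_params(c4 = num("mu_a_c4"), c3 = num("mu_a_c3"),
                       c2 = num("mu_a_c2"), c1 = num("mu_a_c1"),
                       c0 = num("mu_a_c0"), shift = num("mu_a_shift")),
    mu_b = mu_b_params(b2 = num("mu_b_b2"), b1 = num("mu_b_b1"),
                       b0 = num("mu_b_b0")),
    smoking_offset = num("smoking_offset"),
    unilateral_oophorectomy_offset = num("unilateral_oophorectomy_offset"),
    use_modifiers = identical(unname(m[1, "use_modifiers"]), "TRUE")
  )
}

#' @rdname read_ras_model
#' @param model A `ras_model` to serialise.
#' @export
write_ras_model <- function(model, path) {
  stopifnot(inherits(model, "ras_model"))
  fmt <- function(x) format(x, digits = 17, scientific = FALSE, trim = TRUE)
  rec <- c(
    mu_a_shift = fmt(model$mu_a$shift),
    mu_a_c4 = fmt(model$mu_a$c4), mu_a_c3 = fmt(model$mu_a$c3),
    mu_a_c2 = fmt(model$mu_a$c2), mu_a_c1 = fmt(model$mu_a$c1),
    mu_a_c0 = fmt(model$mu_a$c0),
    mu_b_b2 = fmt(model$mu_b$b2), mu_b_b1 = fmt(model$mu_b$b1),
    mu_b_b0 = fmt(model$mu_b$b0),
    smoking_offset = fmt(model$smoking_offset),
    unilateral_oophorectomy_offset = fmt(model$unilateral_oophorectomy_offset),
    use_modifiers = as.character(model$use_modifiers)
  )
  write.dcf(t(as.matrix(rec)), path)
  invisible(path)
}

#' Path of the packaged default model file
#'
#' @return File path of the published-coefficient model shipped with the
#'   package.
#' @export
default_model_path <- function() {
  system.file("extdata", "default_model.dcf", package = "rascore",
              mustWork = TRUE)
}
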