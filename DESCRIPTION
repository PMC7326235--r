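Package: rascore
Title: Continuous Reproductive Ageing Score from Menstrual Questionnaire Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a continuous reproductive ageing score (RAS) on the
    0.00-1.00 scale from three questionnaire items: age, number of menstrual
    periods in the last twelve months, and menstrual regularity. Fuzzy set
    membership functions (a biquadratic exponential over period counts and a
    quadratic logistic over age) are derived from cross-tabulated cohort data
    by nonlinear least squares and combined with the algebraic fuzzy union,
    with optional age modifiers for current smoking and unilateral
    oophorectomy. Includes hormone-based validation against FSH and
    17beta-estradiol cut-offs via ROC analysis, a seeded synthetic cohort
    generator, and a command-line interface for scoring delimited cohort
    files.
License: MIT
Encoding: UTF-8
Imports:
    minpack.lm,
    pROC,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
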