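#' Canonical measure grid
#'
#' The cohort data model records nine measures per recognition test type
#' (item, associate) for every participant: recognition performance (hit
#' rate minus false-alarm rate), memory self-efficacy (MSEQ), postdiction,
#' postdiction accuracy, perceived strategy success, and ratings of
#' difficulty, effort, fatigue and stamina. Columns are ordered test-type
#' major: the nine item-test columns first, then the nine associate-test
#' columns, measures in the order above within each block.
#'
#' @return `measure_names()` returns the 9 measure stems;
#'   `canonical_columns()` the 18 canonical column labels;
#'   `measure_ranges()` a data frame with the legal `lower`/`upper` bound
#'   of each column.
#' @export
measure_names <- function() {
  c("performance", "mseq", "postdiction", "pda", "strategy",
    "difficulty", "effort", "fatigue", "stamina")
}

#' @rdname measure_names
#' @export
test_types <- function() c("item", "assoc")

#' @rdname measure_names
#' @export
canonical_columns <- function() {
  as.vector(vapply(test_types(), function(tt) {
    paste(measure_names(), tt, sep = "_")
  }, character(9L)))
}

#' @rdname measure_names
#' @export
measure_ranges <- function() {
  stem_lo <- c(performance = -1, mseq = 0, postdiction = 0, pda = -1,
               strategy = 0, difficulty = 1, effort = 1, fatigue = 1,
               stamina = 1)
  stem_hi <- c(performance = 1, mseq = 100, postdiction = 100, pda = 1,
               strategy = 100, difficulty = 5, effort = 5, fatigue = 5,
               stamina = 5)
  cols <- canonical_columns()
  stems <- sub("_(item|assoc)$", "", cols)
  data.frame(column = cols,
             lower = unname(stem_lo[stems]),
             upper = unname(stem_hi[stems]),
             stringsAsFactors = FALSE)
}

#' Age-group and stimulus-condition levels
#'
#' @return Character vectors of the factor levels used throughout the
#'   package: `age_levels()` gives `c("young", "old")` and
#'   `condition_levels()` gives the three stimulus conditions.
#' @export
age_levels <- function() c("young", "old")

#' @rdname age_levels
#' @export
condition_levels <- function() c("words", "names", "nonwords")
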