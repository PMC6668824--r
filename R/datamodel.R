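#' Read a cohort table from CSV
#'
#' Ingests a participant table with one row per participant: an identifier,
#' the age group, the stimulus condition, and the 18 measure columns of the
#' canonical grid (see [canonical_columns()]). A long (tidy) layout with one
#' row per participant x measure x test type is also accepted. Every value
#' is validated against the legal range of its measure.
#'
#' @param path Path to a CSV file.
#' @param dialect A list describing the file layout:
#'   `layout` is `"wide"` (default) or `"long"`; `column_map` is an optional
#'   named character vector mapping canonical names (ids, grouping columns
#'   and measure columns) to the names used in the file, so that deposited
#'   tables with arbitrary headers can be ingested without editing them.
#'   For long layouts the value columns are `measure`, `test_type`, `value`.
#' @return A `data.frame` of class `mm_cohort` with columns `id`,
#'   `age_group`, `condition` and the 18 canonical measure columns.
#' @export
read_cohort <- function(path, dialect = list(layout = "wide")) {
  if (!file.exists(path)) stop("cohort file does not exist: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(raw) == 0L) stop("cohort file is empty: ", path)
  layout <- if (is.null(dialect$layout)) "wide" else dialect$layout
  map <- dialect$column_map
  pick <- function(canonical) {
    name <- if (!is.null(map) && canonical %in% names(map)) map[[canonical]] else canonical
    if (!name %in% names(raw)) {
      stop("required column '", name, "' (canonical '", canonical,
           "') missing from ", path)
    }
    raw[[name]]
  }
  if (identical(layout, "wide")) {
    cohort <- data.frame(id = as.character(pick("id")),
                         age_group = as.character(pick("age_group")),
                         condition = as.character(pick("condition")),
                         stringsAsFactors = FALSE)
    for (col in canonical_columns()) cohort[[col]] <- as.numeric(pick(col))
  } else if (identical(layout, "long")) {
    long <- data.frame(id = as.character(pick("id")),
                       age_group = as.character(pick("age_group")),
                       condition = as.character(pick("condition")),
                       measure = as.character(pick("measure")),
                       test_type = as.character(pick("test_type")),
                       value = as.numeric(pick("value")),
                       stringsAsFactors = FALSE)
    long$colname <- paste(long$measure, long$test_type, sep = "_")
    bad <- setdiff(unique(long$colname), canonical_columns())
    if (length(bad)) stop("unknown measure/test_type combinations: ",
                          paste(bad, collapse = ", "))
    ids <- unique(long$id)
    meta <- long[!duplicated(long$id), c("id", "age_group", "condition")]
    wide <- stats::reshape(long[, c("id", "colname", "value")],
                           idvar = "id", timevar = "colname",
                           direction = "wide")
    names(wide) <- sub("^value\\.", "", names(wide))
    missing_cols <- setdiff(canonical_columns(), names(wide))
    if (length(missing_cols)) {
      stop("long cohort file lacks measurements for: ",
           paste(missing_cols, collapse = ", "))
    }
    cohort <- merge(meta, wide, by = "id", sort = FALSE)
    cohort <- cohort[match(ids, cohort$id),
                     c("id", "age_group", "condition", canonical_columns())]
    rownames(cohort) <- NULL
  } else {
    stop("unknown layout '", layout, "'; use 'wide' or 'long'")
  }
  validate_cohort(cohort)
}

#' Validate a cohort table
#'
#' Checks identifiers, factor levels and the legal range of every measure.
#' Called by [read_cohort()] and by the synthetic generator; exported so
#' that programmatically built tables can be checked too.
#'
#' @param cohort A data frame with `id`, `age_group`, `condition` and the 18
#'   canonical measure columns.
#' @return The validated cohort, classed `mm_cohort`, invisibly unchanged.
#' @export
validate_cohort <- function(cohort) {
  need <- c("id", "age_group", "condition", canonical_columns())
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols)) {
    stop("cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(cohort$id)) stop("participant ids must be unique")
  if (any(is.na(cohort$id)) || any(!nzchar(cohort$id))) {
    stop("participant ids must be non-empty")
  }
  if (!all(cohort$age_group %in% age_levels())) {
    stop("age_group must be one of: ", paste(age_levels(), collapse = ", "))
  }
  if (!all(cohort$condition %in% condition_levels())) {
    stop("condition must be one of: ",
         paste(condition_levels(), collapse = ", "))
  }
  rng <- measure_ranges()
  for (i in seq_len(nrow(rng))) {
    col <- rng$column[i]
    v <- cohort[[col]]
    if (any(is.na(v))) {
      stop("missing value in '", col, "' at row id ",
           cohort$id[which(is.na(v))[1L]])
    }
    bad <- which(v < rng$lower[i] | v > rng$upper[i])
    if (length(bad)) {
      stop("value ", v[bad[1L]], " in '", col, "' out of range [",
           rng$lower[i], ", ", rng$upper[i], "] at row id ",
           cohort$id[bad[1L]])
    }
  }
  class(cohort) <- unique(c("mm_cohort", class(cohort)))
  cohort
}

#' Write a cohort table to CSV
#'
#' Wide layout, one row per participant, canonical column names; the file
#' round-trips through [read_cohort()] to identical values.
#'
#' @param cohort A validated cohort table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  cohort <- validate_cohort(cohort)
  utils::write.csv(as.data.frame(cohort)[, c("id", "age_group", "condition",
                                             canonical_columns())],
                   path, row.names = FALSE)
  invisible(path)
}

#' Recognition score: hit rate minus false-alarm rate
#'
#' @param hits,false_alarms Counts of "old" responses to studied and to new
#'   (or recombined) test stimuli.
#' @param n_old,n_new Numbers of studied and new test stimuli.
#' @return `hits / n_old - false_alarms / n_new`, a proportion difference in
#'   \[-1, 1\].
#' @export
recognition_score <- function(hits, false_alarms, n_old, n_new) {
  if (any(n_old <= 0) || any(n_new <= 0)) {
    stop("n_old and n_new must be positive")
  }
  if (any(hits < 0) || any(hits > n_old)) stop("hits must lie in [0, n_old]")
  if (any(false_alarms < 0) || any(false_alarms > n_new)) {
    stop("false_alarms must lie in [0, n_new]")
  }
  hits / n_old - false_alarms / n_new
}

#' Postdiction accuracy
#'
#' A participant's after-test estimate of how much they remembered (0-100),
#' expressed as a proportion, minus their actual percentage correct. For an
#' equal old/new (intact/recombined) recognition test the percentage correct
#' equals `(1 + recognition_score) / 2`, since
#' (hits + correct rejections) / total = (n + hits - FA) / 2n.
#' Negative values indicate underestimation of one's own performance,
#' positive values overestimation.
#'
#' @param postdiction Postdiction rating in percent, 0-100.
#' @param recognition_score Hit rate minus false-alarm rate, in \[-1, 1\].
#' @return Proportion difference in \[-1, 1\].
#' @export
postdiction_accuracy <- function(postdiction, recognition_score) {
  if (any(postdiction < 0) || any(postdiction > 100)) {
    stop("postdiction must lie in [0, 100]")
  }
  if (any(abs(recognition_score) > 1)) {
    stop("recognition_score must lie in [-1, 1]")
  }
  postdiction / 100 - (1 + recognition_score) / 2
}

#' Memory self-efficacy questionnaire score
#'
#' The MSEQ presents graded performance levels (8 for the item
#' questionnaire, 4 for the associate questionnaire); at each level the
#' respondent either declines ("No") or endorses it with a confidence
#' rating from 10 to 100 in steps of 10. The score is the mean confidence
#' across all levels with unendorsed levels scored as zero.
#'
#' @param endorsed Logical vector, one entry per level.
#' @param confidence Numeric vector of the same length; confidence in
#'   \{10, 20, ..., 100\} where `endorsed` is `TRUE`, `NA` elsewhere.
#' @return Score in \[0, 100\].
#' @export
mseq_score <- function(endorsed, confidence) {
  if (length(endorsed) != length(confidence)) {
    stop("endorsed and confidence must have the same length")
  }
  if (!length(endorsed) %in% c(4L, 8L)) {
    stop("expected 4 (associate) or 8 (item) questionnaire levels, got ",
         length(endorsed))
  }
  if (any(endorsed & is.na(confidence))) {
    stop("endorsed level lacks a confidence rating")
  }
  conf <- confidence[endorsed]
  if (any(!conf %in% seq(10, 100, by = 10))) {
    stop("confidence ratings must be in {10, 20, ..., 100}")
  }
  vals <- ifelse(endorsed, confidence, 0)
  mean(vals)
}
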