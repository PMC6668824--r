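#' Build the feature matrix of a cohort
#'
#' Extracts the n x 18 matrix of measure values in canonical column order,
#' with participant ids as row names. The returned object carries a `scale`
#' attribute (`"raw"` or `"zscored"`) so downstream stages can assert what
#' they receive.
#'
#' @param cohort A validated cohort table (see [validate_cohort()]).
#' @return A numeric matrix of class `feature_matrix` with `scale = "raw"`.
#' @export
feature_matrix <- function(cohort) {
  cohort <- validate_cohort(cohort)
  m <- as.matrix(as.data.frame(cohort)[, canonical_columns()])
  rownames(m) <- cohort$id
  new_feature_matrix(m, scale = "raw")
}

new_feature_matrix <- function(m, scale) {
  stopifnot(is.matrix(m), scale %in% c("raw", "zscored"))
  structure(m, scale = scale,
            class = c("feature_matrix", class(m)))
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("feature_matrix: ", nrow(x), " x ", ncol(x),
      " (", attr(x, "scale"), ")\n", sep = "")
  print(utils::head(unclass(x), 3L))
  if (nrow(x) > 3L) cat("...\n")
  invisible(x)
}

#' Z-score normalize a feature matrix
#'
#' Standardizes every column to mean 0 and sample standard deviation 1
#' (denominator n - 1), the scale used for the network inputs and for
#' cluster profiles. Idempotent: standardizing an already standardized
#' matrix returns it unchanged up to floating-point error.
#'
#' @param m A `feature_matrix` (or plain numeric matrix) with at least two
#'   rows and no constant column.
#' @return A `feature_matrix` with `scale = "zscored"`; column labels and
#'   row order preserved.
#' @export
zscore_normalize <- function(m) {
  if (nrow(m) < 2L) stop("z-scoring needs at least 2 rows")
  mu <- colMeans(m)
  sd <- apply(m, 2L, stats::sd)
  zero <- which(sd == 0)
  if (length(zero)) {
    stop("constant column(s) cannot be z-scored: ",
         paste(colnames(m)[zero], collapse = ", "))
  }
  z <- sweep(sweep(unclass(m), 2L, mu, "-"), 2L, sd, "/")
  new_feature_matrix(z, scale = "zscored")
}

#' Select the item or associate feature subset
#'
#' @param m A `feature_matrix` with the 18 canonical columns.
#' @param subset `"all"` (identity), `"item"` (the 9 item-test columns) or
#'   `"associate"` (the 9 associate-test columns). Column order is the
#'   canonical order in every case.
#' @return A `feature_matrix` with the selected columns and the same
#'   `scale` attribute as the input.
#' @export
select_features <- function(m, subset = c("all", "item", "associate")) {
  subset <- match.arg(subset)
  if (!identical(colnames(m), canonical_columns())) {
    stop("expected the 18 canonical columns in canonical order")
  }
  keep <- switch(subset,
                 all = canonical_columns(),
                 item = paste0(measure_names(), "_item"),
                 associate = paste0(measure_names(), "_assoc"))
  new_feature_matrix(unclass(m)[, keep, drop = FALSE],
                     scale = attr(m, "scale"))
}
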