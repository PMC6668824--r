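#' Default per-measure base means and SDs
#'
#' Grand per-variable means and standard deviations on the raw measurement
#' scales, averaged over the two age groups, used as the baseline around
#' which the synthetic generator places its latent clusters.
#'
#' @return A data frame with columns `column`, `mean`, `sd` covering the 18
#'   canonical columns.
#' @export
default_base_stats <- function() {
  stats <- rbind(
    c("performance_item",  0.510,  0.270),
    c("mseq_item",        43.995, 20.780),
    c("postdiction_item", 57.690, 20.385),
    c("pda_item",         -0.180,  0.170),
    c("strategy_item",    51.160, 24.595),
    c("difficulty_item",   3.610,  1.050),
    c("effort_item",       3.850,  0.855),
    c("fatigue_item",      2.335,  1.110),
    c("stamina_item",      1.275,  0.580),
    c("performance_assoc", 0.465,  0.335),
    c("mseq_assoc",       54.030, 20.700),
    c("postdiction_assoc", 54.200, 24.700),
    c("pda_assoc",        -0.190,  0.200),
    c("strategy_assoc",   49.445, 26.765),
    c("difficulty_assoc",  3.775,  1.120),
    c("effort_assoc",      4.020,  0.835),
    c("fatigue_assoc",     2.405,  1.175),
    c("stamina_assoc",     1.360,  0.725))
  out <- data.frame(column = stats[, 1L],
                    mean = as.numeric(stats[, 2L]),
                    sd = as.numeric(stats[, 3L]),
                    stringsAsFactors = FALSE)
  out[match(canonical_columns(), out$column), , drop = FALSE]
}

#' Default latent-cluster effect pattern
#'
#' The 3 x 18 matrix of z-unit offsets defining the three latent
#' participant profiles the generator emulates. Cluster 2 (confident,
#' accurate older adults) is high on item and associate postdictions,
#' perceived strategy success, postdiction accuracy and associate
#' self-efficacy, and low on associate difficulty and item fatigue.
#' Cluster 3 (low-confidence older adults) mirrors Cluster 2 on every one
#' of those variables. Cluster 1 (young-typical) sits at the baseline on
#' the postdiction, strategy and postdiction-accuracy variables, but
#' shares Cluster 2's side of the pattern on associate self-efficacy and
#' associate difficulty (younger adults find the tasks comparatively easy
#' and rate their ability high) and is elevated on item fatigue. Both
#' recognition-performance columns carry zero offsets in all clusters:
#' the latent structure lives in metacognition, not accuracy. Nine
#' variables carry offsets in total; see [offset_variables()].
#'
#' This layout concentrates the young-versus-old separation on the
#' associate measures (self-efficacy and difficulty separate the
#' young-typical cluster from the large older cluster at twice the single
#' offset) while the item measures mainly separate the small older cluster,
#' reproducing the property that associate-task data carry more age
#' information than item-task data.
#'
#' @param magnitude Offset size in z units applied to the affected
#'   variables (default 0.9).
#' @return A 3 x 18 numeric matrix, rows `cluster1..cluster3`, columns the
#'   canonical measure columns.
#' @export
default_effect_pattern <- function(magnitude = 0.9) {
  cols <- canonical_columns()
  pat <- matrix(0, nrow = 3L, ncol = length(cols),
                dimnames = list(paste0("cluster", 1:3), cols))
  mirrored <- c("postdiction_item", "postdiction_assoc",
                "strategy_item", "strategy_assoc",
                "pda_item", "pda_assoc", "mseq_assoc")
  pat["cluster2", mirrored] <- magnitude
  pat["cluster3", mirrored] <- -magnitude
  pat["cluster2", "difficulty_assoc"] <- -magnitude
  pat["cluster3", "difficulty_assoc"] <- magnitude
  # young adults pattern with cluster 2 on the associate belief measures
  pat["cluster1", "mseq_assoc"] <- magnitude
  pat["cluster1", "difficulty_assoc"] <- -magnitude
  # item fatigue: elevated in the young cluster, mirrored across the
  # older clusters
  pat["cluster1", "fatigue_item"] <- magnitude
  pat["cluster2", "fatigue_item"] <- -magnitude
  pat["cluster3", "fatigue_item"] <- magnitude
  pat
}

#' Columns carrying a non-zero offset in the default pattern
#'
#' @param pattern An effect-pattern matrix as returned by
#'   [default_effect_pattern()].
#' @return Character vector of column labels with any non-zero offset.
#' @export
offset_variables <- function(pattern = default_effect_pattern()) {
  colnames(pattern)[colSums(pattern != 0) > 0]
}

#' Synthetic cohort configuration
#'
#' @param n_young,n_old Group sizes (defaults 57 and 49).
#' @param old_cluster_sizes Sizes of the two predominantly-old latent
#'   clusters (defaults 12 and 36); any remaining older adults cross over
#'   into the young-typical cluster 1.
#' @param crossover_young_into_cluster2 Number of younger adults generated
#'   with the cluster-2 profile (default 1).
#' @param effect_pattern 3 x 18 z-offset matrix; see
#'   [default_effect_pattern()].
#' @param base_stats Per-column raw-scale mean/SD table; see
#'   [default_base_stats()].
#' @param residual_sd Within-cluster residual SD in z units (default 1).
#' @param seed Integer seed making the cohort reproducible.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_young = 57L, n_old = 49L,
                             old_cluster_sizes = c(12L, 36L),
                             crossover_young_into_cluster2 = 1L,
                             effect_pattern = default_effect_pattern(),
                             base_stats = default_base_stats(),
                             residual_sd = 1.0, seed = 1L) {
  if (residual_sd <= 0) stop("residual_sd must be positive")
  if (length(old_cluster_sizes) != 2L || any(old_cluster_sizes < 0)) {
    stop("old_cluster_sizes must be two non-negative counts")
  }
  if (sum(old_cluster_sizes) > n_old) {
    stop("old cluster sizes (", sum(old_cluster_sizes),
         ") exceed n_old (", n_old, ")")
  }
  if (crossover_young_into_cluster2 > n_young) {
    stop("more young crossovers than young participants")
  }
  if (!identical(dim(effect_pattern), c(3L, 18L))) {
    stop("effect_pattern must be 3 x 18")
  }
  if (!identical(base_stats$column, canonical_columns())) {
    stop("base_stats must cover the 18 canonical columns in order")
  }
  structure(list(n_young = as.integer(n_young), n_old = as.integer(n_old),
                 old_cluster_sizes = as.integer(old_cluster_sizes),
                 crossover_young_into_cluster2 =
                   as.integer(crossover_young_into_cluster2),
                 effect_pattern = effect_pattern, base_stats = base_stats,
                 residual_sd = residual_sd, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic cohort with latent three-cluster structure
#'
#' Draws each participant's latent cluster per the configuration, then each
#' measure as `base mean + base SD * (cluster offset + N(0, residual_sd))`,
#' clipped to the measure's legal range and rounded to 6 decimals (the
#' declared precision, making CSV round-trips lossless). Measures are
#' independent given the cluster. Stimulus condition is assigned uniformly
#' at random and carried as metadata only.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `synthetic_cohort` with elements `cohort` (a
#'   validated cohort table), `truth` (data frame mapping `id` to the
#'   latent `cluster`), `n_clipped` (count of clipped draws) and `config`.
#' @export
generate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n_young <- config$n_young
  n_old <- config$n_old
  n <- n_young + n_old
  ids <- c(sprintf("y%03d", seq_len(n_young)),
           sprintf("o%03d", seq_len(n_old)))
  age <- rep(age_levels(), c(n_young, n_old))

  cluster <- integer(n)
  xo_young <- sample(seq_len(n_young), config$crossover_young_into_cluster2)
  cluster[seq_len(n_young)] <- 1L
  cluster[xo_young] <- 2L
  old_idx <- sample(n_young + seq_len(n_old))  # random order among old
  sizes <- config$old_cluster_sizes
  cluster[old_idx[seq_len(sizes[1L])]] <- 2L
  cluster[old_idx[sizes[1L] + seq_len(sizes[2L])]] <- 3L
  rest <- old_idx[-seq_len(sum(sizes))]
  cluster[rest] <- 1L  # remaining older adults cross into cluster 1

  condition <- sample(condition_levels(), n, replace = TRUE)
  bs <- config$base_stats
  rng <- measure_ranges()
  vals <- matrix(NA_real_, n, 18L,
                 dimnames = list(NULL, canonical_columns()))
  n_clipped <- 0L
  for (j in seq_len(18L)) {
    z <- config$effect_pattern[cluster, j] +
      stats::rnorm(n, 0, config$residual_sd)
    x <- bs$mean[j] + bs$sd[j] * z
    lo <- rng$lower[j]; hi <- rng$upper[j]
    n_clipped <- n_clipped + sum(x < lo | x > hi)
    vals[, j] <- round(pmin(pmax(x, lo), hi), 6L)
  }
  cohort <- data.frame(id = ids, age_group = age, condition = condition,
                       stringsAsFactors = FALSE)
  cohort <- cbind(cohort, as.data.frame(vals))
  cohort <- validate_cohort(cohort)
  structure(list(cohort = cohort,
                 truth = data.frame(id = ids, cluster = cluster,
                                    stringsAsFactors = FALSE),
                 n_clipped = n_clipped,
                 config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort: ", nrow(x$cohort), " participants (",
      sum(x$cohort$age_group == "young"), " young / ",
      sum(x$cohort$age_group == "old"), " old), truth clusters ",
      paste(table(x$truth$cluster), collapse = "/"),
      ", ", x$n_clipped, " clipped draws\n", sep = "")
  invisible(x)
}
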