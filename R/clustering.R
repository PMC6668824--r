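#' k-means over hidden-unit activations
#'
#' Lloyd's algorithm with k-means++ seeding, restarted `restarts` times;
#' the solution with the smallest within-cluster sum of squares wins.
#' Within every restart the inertia is checked to be non-increasing across
#' Lloyd iterations; a centroid that loses all its points is re-seeded to
#' the point farthest from its assigned centroid.
#'
#' @param points n x d numeric matrix (here: hidden activations).
#' @param k Number of clusters.
#' @param restarts Number of k-means++ restarts (default 50).
#' @param seed Integer seed; the whole procedure is deterministic under it.
#' @param max_iter Lloyd iteration cap per restart (default 300).
#' @param tol Relative inertia-change convergence threshold (default
#'   1e-12).
#' @return A list of class `cluster_solution` with `assignments` (length
#'   n, values 1..k), `centroids` (k x d), `tot_withinss`, `restarts`,
#'   `seed` and `restart_inertias`.
#' @export
kmeans_latent <- function(points, k = 3L, restarts = 50L, seed = 1L,
                          max_iter = 300L, tol = 1e-12) {
  points <- unclass(as.matrix(points))
  n <- nrow(points)
  if (k < 1L) stop("k must be at least 1")
  if (n < k) stop("need at least k = ", k, " points, got ", n)
  if (restarts < 1L) stop("restarts must be at least 1")
  set.seed(seed)
  best <- NULL
  inertias <- numeric(restarts)
  for (r in seq_len(restarts)) {
    fit <- .kmeans_once(points, k, max_iter, tol)
    inertias[r] <- fit$tot_withinss
    if (is.null(best) || fit$tot_withinss < best$tot_withinss) best <- fit
  }
  structure(list(assignments = best$assignments,
                 centroids = best$centroids,
                 tot_withinss = best$tot_withinss,
                 restarts = restarts, seed = seed,
                 restart_inertias = inertias),
            class = "cluster_solution")
}

# squared Euclidean distances from every point to every centroid
.sqdist <- function(points, centroids) {
  outer(rowSums(points^2), rep(1, nrow(centroids))) +
    outer(rep(1, nrow(points)), rowSums(centroids^2)) -
    2 * points %*% t(centroids)
}

.kmeanspp_init <- function(points, k) {
  n <- nrow(points)
  idx <- integer(k)
  idx[1L] <- sample.int(n, 1L)
  if (k > 1L) {
    d2 <- .sqdist(points, points[idx[1L], , drop = FALSE])[, 1L]
    for (j in 2:k) {
      d2 <- pmax(d2, 0)
      idx[j] <- if (sum(d2) > 0) {
        sample.int(n, 1L, prob = d2)
      } else {
        sample.int(n, 1L)
      }
      d2 <- pmin(d2, .sqdist(points, points[idx[j], , drop = FALSE])[, 1L])
    }
  }
  points[idx, , drop = FALSE]
}

.kmeans_once <- function(points, k, max_iter, tol) {
  centroids <- .kmeanspp_init(points, k)
  prev_inertia <- Inf
  assignments <- NULL
  for (iter in seq_len(max_iter)) {
    d2 <- pmax(.sqdist(points, centroids), 0)
    assignments <- max.col(-d2, ties.method = "first")
    for (j in seq_len(k)) {       # re-seed any emptied centroid
      if (!any(assignments == j)) {
        far <- which.max(d2[cbind(seq_len(nrow(points)), assignments)])
        centroids[j, ] <- points[far, ]
        assignments[far] <- j
      }
    }
    inertia <- sum(d2[cbind(seq_along(assignments), assignments)])
    if (inertia > prev_inertia + 1e-8 * max(1, prev_inertia)) {
      stop("k-means inertia increased across an iteration")
    }
    done <- is.finite(prev_inertia) &&
      (prev_inertia - inertia) <= tol * max(1, prev_inertia)
    prev_inertia <- inertia
    for (j in seq_len(k)) {
      centroids[j, ] <- colMeans(points[assignments == j, , drop = FALSE])
    }
    if (done) break
  }
  d2 <- pmax(.sqdist(points, centroids), 0)
  assignments <- max.col(-d2, ties.method = "first")
  structure(list(assignments = assignments, centroids = centroids,
                 tot_withinss =
                   sum(d2[cbind(seq_along(assignments), assignments)])),
            class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat("cluster_solution: k = ", nrow(x$centroids), ", sizes ",
      paste(tabulate(x$assignments, nrow(x$centroids)), collapse = "/"),
      sprintf(", inertia %.4g\n", x$tot_withinss), sep = "")
  invisible(x)
}

#' Canonical labelling of the three-cluster solution
#'
#' k-means labels are arbitrary; this fixes them to the convention used
#' throughout: cluster 1 is the cluster with the highest proportion of
#' younger adults; of the remaining two, cluster 2 is the one with the
#' higher mean z-scored associate postdiction accuracy (the confident,
#' accurate older group), cluster 3 the other. For `k != 3` the solution
#' is returned unchanged with a warning, since the canonical names are
#' defined only for the three-cluster design.
#'
#' @param solution A `cluster_solution` with k = 3.
#' @param age_group True labels, one per point.
#' @param features_z z-scored 18-column `feature_matrix` (row order must
#'   match the clustered points).
#' @return The solution with relabelled `assignments` and reordered
#'   `centroids`.
#' @export
canonicalize_clusters <- function(solution, age_group, features_z) {
  k <- nrow(solution$centroids)
  if (k != 3L) {
    warning("canonical labels are defined for k = 3; returning as-is")
    return(solution)
  }
  a <- solution$assignments
  prop_young <- vapply(1:3, function(j) mean(age_group[a == j] == "young"),
                       numeric(1L))
  lab1 <- which.max(prop_young)
  rest <- setdiff(1:3, lab1)
  pda <- unclass(features_z)[, "pda_assoc"]
  mean_pda <- vapply(rest, function(j) mean(pda[a == j]), numeric(1L))
  lab2 <- rest[which.max(mean_pda)]
  lab3 <- setdiff(rest, lab2)
  perm <- integer(3L)
  perm[c(lab1, lab2, lab3)] <- 1:3
  solution$assignments <- perm[a]
  solution$centroids <- solution$centroids[order(perm), , drop = FALSE]
  solution
}

#' Per-cluster profiles of the z-scored measures
#'
#' Mean and standard error (sample SD / sqrt(cluster size)) of every
#' z-scored input variable within each cluster. Values above zero mean
#' "above the sample average" on that measure. For a cluster of size 1 the
#' SE is reported as `NA`.
#'
#' @param features_z z-scored `feature_matrix`.
#' @param assignments Integer cluster labels, one per row.
#' @return A data frame with columns `cluster`, `variable`, `mean`, `se`,
#'   `n`.
#' @export
cluster_profiles <- function(features_z, assignments) {
  z <- unclass(features_z)
  if (length(assignments) != nrow(z)) stop("one assignment per row needed")
  ks <- sort(unique(assignments))
  out <- do.call(rbind, lapply(ks, function(j) {
    zi <- z[assignments == j, , drop = FALSE]
    nj <- nrow(zi)
    data.frame(cluster = j, variable = colnames(z),
               mean = colMeans(zi),
               se = if (nj >= 2L) {
                 apply(zi, 2L, stats::sd) / sqrt(nj)
               } else {
                 NA_real_
               },
               n = nj, stringsAsFactors = FALSE, row.names = NULL)
  }))
  out
}

#' One-way between-cluster ANOVAs on every input variable
#'
#' For each of the 18 (z-scored) input variables, a one-way independent
#' measures ANOVA compares the clusters, with a Bonferroni correction for
#' the family of 18 tests and partial eta squared
#' (SS_between / (SS_between + SS_within)) as the effect size. The fits
#' are delegated to `stats::lm`/`stats::anova`.
#'
#' @param features_z z-scored `feature_matrix`.
#' @param assignments Integer cluster labels, one per row.
#' @param m Bonferroni family size (default `ncol(features_z)`).
#' @param alpha Family-wise error rate defining the significance flag
#'   (raw p below `alpha / m`; default 0.05, giving the p < .0028
#'   criterion for 18 tests).
#' @return A data frame with one row per variable: per-cluster means, `F`,
#'   `df1`, `df2`, `p_raw`, `p_bonferroni`, `partial_eta_sq`,
#'   `significant`.
#' @export
cluster_feature_anovas <- function(features_z, assignments,
                                   m = ncol(features_z), alpha = 0.05) {
  z <- unclass(features_z)
  if (length(assignments) != nrow(z)) stop("one assignment per row needed")
  sizes <- table(assignments)
  if (length(sizes) < 2L || any(sizes < 2L)) {
    stop("every cluster needs at least 2 members; sizes: ",
         paste(names(sizes), sizes, sep = "=", collapse = ", "))
  }
  g <- factor(assignments)
  rows <- lapply(colnames(z), function(v) {
    tab <- stats::anova(stats::lm(z[, v] ~ g))
    ssb <- tab$`Sum Sq`[1L]
    ssw <- tab$`Sum Sq`[2L]
    means <- tapply(z[, v], g, mean)
    out <- data.frame(variable = v, F = tab$`F value`[1L],
                      df1 = tab$Df[1L], df2 = tab$Df[2L],
                      p_raw = tab$`Pr(>F)`[1L],
                      partial_eta_sq = ssb / (ssb + ssw),
                      stringsAsFactors = FALSE)
    for (j in names(means)) out[[paste0("mean_cluster", j)]] <- means[[j]]
    out
  })
  res <- do.call(rbind, rows)
  res$p_bonferroni <- stats::p.adjust(res$p_raw, "bonferroni", n = m)
  res$significant <- res$p_raw < alpha / m
  res
}

#' Cluster-by-age composition table
#'
#' @param assignments Integer cluster labels.
#' @param age_group True labels, one per point.
#' @return A k x 2 integer table of counts (rows clusters, columns
#'   young/old); marginals equal the group sizes.
#' @export
composition_table <- function(assignments, age_group) {
  table(cluster = factor(assignments),
        age_group = factor(age_group, levels = age_levels()))
}
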