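#' Split-plot mixed ANOVA on recognition scores
#'
#' The classical 2 x 3 x 2 split-plot decomposition with Age (young, old)
#' and Stimulus Type (words, names, nonwords) as between-subjects factors
#' and Test Type (item, associate) as the within-subjects factor. Each
#' between-subjects effect is tested against the subjects-within-groups
#' error; each within-subjects effect against the TestType-by-subjects
#' error. Unequal cell sizes are handled by the unweighted-means solution:
#' effect sums of squares are computed from unweighted cell means with the
#' harmonic mean of the cell sizes as the effective per-cell n. On a
#' balanced design this reduces to the textbook decomposition and the
#' effect and error sums of squares add up to the total.
#'
#' @param score_item,score_assoc Per-subject recognition scores on the two
#'   test types.
#' @param age Factor-like vector of `"young"`/`"old"`.
#' @param stimulus Factor-like vector of stimulus conditions.
#' @return A data frame of class `mixed_anova` with one row per effect and
#'   error stratum: `effect`, `stratum`, `SS`, `df`, `MS`, `F`, `p`,
#'   `partial_eta_sq`.
#' @export
mixed_anova <- function(score_item, score_assoc, age, stimulus) {
  n <- length(score_item)
  if (length(score_assoc) != n || length(age) != n ||
      length(stimulus) != n) {
    stop("all inputs must have one entry per subject")
  }
  if (any(is.na(score_item)) || any(is.na(score_assoc))) {
    stop("missing within-subject score for subject ",
         which(is.na(score_item) | is.na(score_assoc))[1L])
  }
  A <- factor(age)
  B <- factor(stimulus)
  if (nlevels(A) < 2L || nlevels(B) < 2L) {
    stop("both between-subjects factors need at least two levels")
  }
  if (any(table(A, B) == 0L)) stop("every Age x Stimulus cell needs data")
  y <- cbind(item = score_item, assoc = score_assoc)
  p <- nlevels(A); q <- nlevels(B); t <- ncol(y)

  subj_mean <- rowMeans(y)
  cell <- interaction(A, B, drop = FALSE)
  n_ab <- as.vector(table(cell))
  n_h <- (p * q) / sum(1 / n_ab)

  M_ab <- matrix(tapply(subj_mean, list(A, B), mean), p, q)
  M_abt <- array(NA_real_, c(p, q, t))
  for (tt in seq_len(t)) {
    M_abt[, , tt] <- matrix(tapply(y[, tt], list(A, B), mean), p, q)
  }
  A_a <- rowMeans(M_ab); B_b <- colMeans(M_ab); G <- mean(M_ab)
  W_t <- apply(M_abt, 3L, mean)

  SS_A <- t * n_h * q * sum((A_a - G)^2)
  SS_B <- t * n_h * p * sum((B_b - G)^2)
  SS_AB <- t * n_h *
    sum((M_ab - outer(A_a, rep(1, q)) - outer(rep(1, p), B_b) + G)^2)
  SS_S <- t * sum((subj_mean - M_ab[cbind(as.integer(A), as.integer(B))])^2)

  SS_T <- n_h * p * q * sum((W_t - G)^2)
  M_at <- apply(M_abt, c(1L, 3L), mean)
  M_bt <- apply(M_abt, c(2L, 3L), mean)
  SS_TA <- n_h * q *
    sum((M_at - outer(A_a, rep(1, t)) - outer(rep(1, p), W_t) + G)^2)
  SS_TB <- n_h * p *
    sum((M_bt - outer(B_b, rep(1, t)) - outer(rep(1, q), W_t) + G)^2)
  resid3 <- M_abt
  for (tt in seq_len(t)) {
    resid3[, , tt] <- M_abt[, , tt] - outer(M_at[, tt], rep(1, q)) -
      outer(rep(1, p), M_bt[, tt]) - M_ab +
      outer(A_a, rep(1, q)) + outer(rep(1, p), B_b) + W_t[tt] - G
  }
  SS_TAB <- n_h * sum(resid3^2)
  cell_idx <- cbind(as.integer(A), as.integer(B))
  SS_TS <- 0
  for (tt in seq_len(t)) {
    SS_TS <- SS_TS +
      sum((y[, tt] - subj_mean - M_abt[, , tt][cell_idx] +
             M_ab[cell_idx])^2)
  }

  df_S <- n - p * q
  df_TS <- df_S * (t - 1L)
  MS_S <- SS_S / df_S
  MS_TS <- SS_TS / df_TS
  eff <- function(name, stratum, SS, df, MS_err, df_err) {
    MS <- SS / df
    F <- if (SS == 0) 0 else MS / MS_err  # a null effect is F = 0 even
    # when the error stratum is also degenerate
    data.frame(effect = name, stratum = stratum, SS = SS, df = df,
               MS = MS, F = F,
               p = stats::pf(F, df, df_err, lower.tail = FALSE),
               partial_eta_sq = SS / (SS + MS_err * df_err),
               stringsAsFactors = FALSE)
  }
  out <- rbind(
    eff("Age", "between", SS_A, p - 1L, MS_S, df_S),
    eff("Stimulus", "between", SS_B, q - 1L, MS_S, df_S),
    eff("Age:Stimulus", "between", SS_AB, (p - 1L) * (q - 1L), MS_S, df_S),
    data.frame(effect = "Subjects(Age:Stimulus)", stratum = "between",
               SS = SS_S, df = df_S, MS = MS_S, F = NA, p = NA,
               partial_eta_sq = NA, stringsAsFactors = FALSE),
    eff("TestType", "within", SS_T, t - 1L, MS_TS, df_TS),
    eff("TestType:Age", "within", SS_TA, (t - 1L) * (p - 1L), MS_TS,
        df_TS),
    eff("TestType:Stimulus", "within", SS_TB, (t - 1L) * (q - 1L), MS_TS,
        df_TS),
    eff("TestType:Age:Stimulus", "within", SS_TAB,
        (t - 1L) * (p - 1L) * (q - 1L), MS_TS, df_TS),
    data.frame(effect = "TestType:Subjects", stratum = "within",
               SS = SS_TS, df = df_TS, MS = MS_TS, F = NA, p = NA,
               partial_eta_sq = NA, stringsAsFactors = FALSE))
  class(out) <- c("mixed_anova", class(out))
  out
}

#' Pooled-variance two-sample t test from summary statistics
#'
#' Student's two-sample t with pooled variance, callable from the printed
#' mean/SD/n summaries of a results table or, via [pooled_t_test_raw()],
#' from raw vectors. The degrees of freedom are `n1 + n2 - 2`.
#'
#' @param m1,sd1,n1 Mean, SD and size of group 1.
#' @param m2,sd2,n2 Mean, SD and size of group 2.
#' @param m Bonferroni family size for the adjusted p (default 1: no
#'   correction).
#' @return A list of class `t_test_result`: `t`, `df`, `p_two_tailed`,
#'   `p_bonferroni`, `cohens_d` (average-SD convention, see
#'   [cohens_d_avg_sd()]).
#' @export
pooled_t_test <- function(m1, sd1, n1, m2, sd2, n2, m = 1L) {
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 observations")
  if (sd1 == 0 && sd2 == 0) stop("zero variance in both groups")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  t_stat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  p <- 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE)
  structure(list(t = t_stat, df = df, p_two_tailed = p,
                 p_bonferroni = min(1, m * p),
                 cohens_d = cohens_d_avg_sd(m1, sd1, m2, sd2)),
            class = "t_test_result")
}

#' @rdname pooled_t_test
#' @param x,y Raw observation vectors for the two groups.
#' @export
pooled_t_test_raw <- function(x, y, m = 1L) {
  pooled_t_test(mean(x), stats::sd(x), length(x),
                mean(y), stats::sd(y), length(y), m = m)
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("t(%d) = %.3f, p = %.4g (Bonferroni %.4g), d = %.3f\n",
              x$df, x$t, x$p_two_tailed, x$p_bonferroni, x$cohens_d))
  invisible(x)
}

#' Cohen's d with the average-SD standardizer
#'
#' `|m1 - m2| / ((sd1 + sd2) / 2)`: the absolute mean difference divided by
#' the plain average of the two group SDs (not the pooled SD). This is the
#' convention used for the demographic and measure tables this package
#' reproduces; the pooled-SD variant is available via `pooled = TRUE`.
#'
#' @param m1,sd1,m2,sd2 Group means and SDs.
#' @param n1,n2 Group sizes, required only when `pooled = TRUE`.
#' @param pooled Use the pooled-SD standardizer instead.
#' @return Non-negative effect size; 0 when the means are equal.
#' @export
cohens_d_avg_sd <- function(m1, sd1, m2, sd2, n1 = NULL, n2 = NULL,
                            pooled = FALSE) {
  if (sd1 < 0 || sd2 < 0) stop("SDs must be non-negative")
  if (sd1 == 0 && sd2 == 0) stop("both SDs are zero")
  denom <- if (pooled) {
    if (is.null(n1) || is.null(n2)) stop("pooled SD needs n1 and n2")
    sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  } else {
    (sd1 + sd2) / 2
  }
  abs(m1 - m2) / denom
}

#' Post-hoc stimulus-type comparisons of recognition scores
#'
#' Pairwise pooled t tests between the three stimulus conditions, where
#' each subject contributes two observations (the item and the associate
#' score are entered as separate observations, so a pair of conditions
#' with n1 and n2 subjects is tested on 2*n1 + 2*n2 - 2 degrees of
#' freedom). Bonferroni-corrected for the family of 3 tests.
#'
#' @param score_item,score_assoc Per-subject recognition scores.
#' @param stimulus Stimulus condition per subject.
#' @return A data frame with one row per condition pair: `comparison`,
#'   group means, `t`, `df`, `p_two_tailed`, `p_bonferroni`, `cohens_d`.
#' @export
posthoc_stimulus_tests <- function(score_item, score_assoc, stimulus) {
  conds <- condition_levels()
  if (!all(conds %in% stimulus)) {
    stop("all three stimulus conditions must be present")
  }
  obs <- data.frame(score = c(score_item, score_assoc),
                    stimulus = rep(stimulus, 2L),
                    stringsAsFactors = FALSE)
  pairs <- utils::combn(conds, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    c1 <- pairs[1L, i]; c2 <- pairs[2L, i]
    x <- obs$score[obs$stimulus == c1]
    y <- obs$score[obs$stimulus == c2]
    tt <- pooled_t_test_raw(x, y, m = 3L)
    data.frame(comparison = paste(c1, "vs", c2),
               mean1 = mean(x), mean2 = mean(y),
               t = tt$t, df = tt$df, p_two_tailed = tt$p_two_tailed,
               p_bonferroni = tt$p_bonferroni, cohens_d = tt$cohens_d,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Bonferroni adjustment
#'
#' @param p Vector of raw p values.
#' @param m Family size (at least `length(p)`).
#' @return `pmin(1, m * p)` via `stats::p.adjust`.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1)) stop("p values must lie in [0, 1]")
  if (m < length(p)) stop("family size m must be >= number of tests")
  stats::p.adjust(p, method = "bonferroni", n = m)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise error rate.
#' @param m Family size.
#' @return The per-test raw-p threshold `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) alpha / m

#' Young-versus-old t tests on every measure
#'
#' The table-style univariate comparison: a pooled two-sample t test of
#' younger versus older adults on each of the 18 measure columns,
#' Bonferroni-corrected for the family of 18 tests.
#'
#' @param cohort A validated cohort table.
#' @return A data frame with one row per measure column: group means and
#'   SDs, `t`, `df`, `p_two_tailed`, `p_bonferroni`, `cohens_d`,
#'   `significant`.
#' @export
age_t_table <- function(cohort) {
  cohort <- validate_cohort(cohort)
  young <- cohort$age_group == "young"
  cols <- canonical_columns()
  rows <- lapply(cols, function(col) {
    x <- cohort[[col]][young]
    y <- cohort[[col]][!young]
    tt <- pooled_t_test_raw(x, y, m = length(cols))
    data.frame(variable = col, mean_young = mean(x),
               sd_young = stats::sd(x), mean_old = mean(y),
               sd_old = stats::sd(y), t = tt$t, df = tt$df,
               p_two_tailed = tt$p_two_tailed,
               p_bonferroni = tt$p_bonferroni, cohens_d = tt$cohens_d,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p_two_tailed <
    bonferroni_threshold(0.05, length(cols))
  out
}
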