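# Brute-force split-plot fixture: balanced 2 x 3 x 2 design, 2 per cell.
balanced_fixture <- function(seed = 1) {
  set.seed(seed)
  d <- expand.grid(subj_in_cell = 1:2,
                   age = c("young", "old"),
                   stim = c("words", "names", "nonwords"))
  n <- nrow(d)
  d$item <- rnorm(n) + (d$age == "old") * 0.5 + as.numeric(d$stim) * 0.3
  d$assoc <- d$item + rnorm(n, sd = 0.5) - 0.2
  d
}

# Independent oracle: stats::aov with an Error(subject) stratum (Type I
# sequential SS, which equals the unweighted-means solution when balanced).
aov_oracle <- function(d) {
  long <- rbind(data.frame(d, test = "item", score = d$item),
                data.frame(d, test = "assoc", score = d$assoc))
  long$subject <- factor(rep(seq_len(nrow(d)), 2))
  fit <- summary(stats::aov(
    score ~ age * stim * test + Error(subject / test), data = long))
  list(between = as.data.frame(fit[["Error: subject"]][[1]]),
       within = as.data.frame(fit[["Error: subject:test"]][[1]]))
}

test_that("split-plot decomposition matches the aov oracle when balanced", {
  for (seed in 1:3) {
    d <- balanced_fixture(seed)
    got <- mixed_anova(d$item, d$assoc, d$age, d$stim)
    ora <- aov_oracle(d)
    pick <- function(tab, pat) tab[grepl(pat, trimws(rownames(tab))), ]
    expect_equal(got$SS[got$effect == "Age"],
                 pick(ora$between, "^age$")$`Sum Sq`, tolerance = 1e-10)
    expect_equal(got$SS[got$effect == "Stimulus"],
                 pick(ora$between, "^stim$")$`Sum Sq`, tolerance = 1e-10)
    expect_equal(got$SS[got$effect == "Age:Stimulus"],
                 pick(ora$between, "^age:stim$")$`Sum Sq`,
                 tolerance = 1e-10)
    expect_equal(got$SS[got$effect == "Subjects(Age:Stimulus)"],
                 pick(ora$between, "Residuals")$`Sum Sq`,
                 tolerance = 1e-10)
    expect_equal(got$SS[got$effect == "TestType"],
                 pick(ora$within, "^test$")$`Sum Sq`, tolerance = 1e-10)
    expect_equal(got$SS[got$effect == "TestType:Age"],
                 pick(ora$within, "^age:test$")$`Sum Sq`,
                 tolerance = 1e-10)
    expect_equal(got$SS[got$effect == "TestType:Stimulus"],
                 pick(ora$within, "^stim:test$")$`Sum Sq`,
                 tolerance = 1e-10)
    expect_equal(got$SS[got$effect == "TestType:Age:Stimulus"],
                 pick(ora$within, "^age:stim:test$")$`Sum Sq`,
                 tolerance = 1e-10)
    expect_equal(got$SS[got$effect == "TestType:Subjects"],
                 pick(ora$within, "Residuals")$`Sum Sq`,
                 tolerance = 1e-10)
    expect_equal(got$F[got$effect == "Stimulus"],
                 pick(ora$between, "^stim$")$`F value`, tolerance = 1e-10)
  }
})

test_that("split-plot SS conserve the total on balanced random data", {
  for (seed in 4:6) {
    d <- balanced_fixture(seed)
    got <- mixed_anova(d$item, d$assoc, d$age, d$stim)
    total <- sum((c(d$item, d$assoc) - mean(c(d$item, d$assoc)))^2)
    expect_equal(sum(got$SS), total, tolerance = 1e-9)
  }
})

test_that("split-plot handles nulls, unbalanced cells and bad input", {
  d <- balanced_fixture(1)
  same <- rep(0.3, nrow(d))
  got <- mixed_anova(same, same, d$age, d$stim)
  expect_true(all(got$F[!is.na(got$F)] == 0))

  # unbalanced 2 x 3 (sizes 2..4 per cell): dfs follow N and eta_p^2 is
  # consistent with its defining SS ratio
  set.seed(9)
  d2 <- d[sample(nrow(d), nrow(d), replace = FALSE), ]
  d2 <- rbind(d2, d2[d2$age == "old" & d2$stim == "words", ][1, ])
  d2$item[nrow(d2)] <- d2$item[nrow(d2)] + 0.1
  got2 <- mixed_anova(d2$item, d2$assoc, d2$age, d2$stim)
  N <- nrow(d2)
  expect_equal(got2$df[got2$effect == "Subjects(Age:Stimulus)"], N - 6)
  err <- got2[got2$effect == "Subjects(Age:Stimulus)", ]
  age <- got2[got2$effect == "Age", ]
  expect_equal(age$partial_eta_sq, age$SS / (age$SS + err$SS),
               tolerance = 1e-12)

  expect_error(mixed_anova(d$item[-1], d$assoc, d$age, d$stim), "entry")
  expect_error(mixed_anova(replace(d$item, 2, NA), d$assoc, d$age,
                           d$stim), "missing")
  expect_error(mixed_anova(d$item, d$assoc, d$age,
                           rep("words", nrow(d))), "levels")
  unbal <- d; unbal$stim <- as.character(unbal$stim)
  unbal$stim[unbal$age == "old" & unbal$stim == "words"] <- "names"
  expect_error(mixed_anova(unbal$item, unbal$assoc, unbal$age,
                           unbal$stim), "cell")
})

test_that("pooled t reproduces printed statistics and its raw-data twin", {
  # item-test fatigue summaries: young (2.79, 1.13, 57), old (1.88, 1.09, 49)
  r <- pooled_t_test(2.79, 1.13, 57, 1.88, 1.09, 49, m = 18)
  expect_equal(r$df, 104)
  expect_equal(r$t, 4.207, tolerance = 0.01 / 4.207)
  expect_equal(round(r$cohens_d, 2), 0.82)
  # significant under the Bonferroni threshold for 18 tests
  expect_lt(r$p_two_tailed, bonferroni_threshold(0.05, 18))

  # summary form equals the raw-vector form
  set.seed(12)
  x <- rnorm(14, 1, 2); y <- rnorm(9, 0, 1.5)
  a <- pooled_t_test(mean(x), sd(x), 14, mean(y), sd(y), 9)
  b <- pooled_t_test_raw(x, y)
  expect_equal(a$t, b$t, tolerance = 1e-12)
  expect_equal(a$p_two_tailed, b$p_two_tailed, tolerance = 1e-12)
  # and matches stats::t.test with pooled variance
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(b$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(b$p_two_tailed, ref$p.value, tolerance = 1e-12)

  # antisymmetry under group swap
  sw <- pooled_t_test_raw(y, x)
  expect_equal(sw$t, -b$t, tolerance = 1e-12)
  expect_equal(sw$p_two_tailed, b$p_two_tailed, tolerance = 1e-12)
  expect_equal(pooled_t_test(1, 1, 5, 1, 1, 5)$t, 0)
  expect_error(pooled_t_test(1, 0, 5, 1, 0, 5), "variance")
})

test_that("Cohen's d uses the average-SD convention of the tables", {
  expect_equal(round(cohens_d_avg_sd(12.91, 0.96, 16.17, 2.36), 2), 1.96)
  expect_equal(round(cohens_d_avg_sd(8.86, 1.29, 7.31, 2.41), 2), 0.84)
  expect_equal(round(cohens_d_avg_sd(22.07, 4.16, 29.06, 4.99), 2), 1.53)
  expect_equal(cohens_d_avg_sd(3, 1, 3, 2), 0)
  # the pooled-SD convention does NOT reproduce the education value,
  # pinning which standardizer the tables used
  pooled <- cohens_d_avg_sd(12.91, 0.96, 16.17, 2.36, n1 = 57, n2 = 49,
                            pooled = TRUE)
  expect_equal(round(pooled, 2), 1.86)
  expect_error(cohens_d_avg_sd(1, 0, 2, 0), "zero")
})

test_that("post-hoc stimulus tests pool item and associate observations", {
  set.seed(3)
  stim <- rep(c("words", "names", "nonwords"), c(36, 36, 34))
  mu <- c(words = 0.69, names = 0.43, nonwords = 0.33)
  item <- rnorm(106, mu[stim], 0.2)
  assoc <- rnorm(106, mu[stim], 0.2)
  got <- posthoc_stimulus_tests(item, assoc, stim)
  expect_equal(got$df[got$comparison == "words vs names"], 142)
  expect_equal(got$df[got$comparison == "words vs nonwords"], 138)
  expect_equal(got$df[got$comparison == "names vs nonwords"], 138)
  expect_gt(got$mean1[got$comparison == "words vs names"],
            got$mean2[got$comparison == "words vs names"])
  expect_equal(got$p_bonferroni, pmin(1, 3 * got$p_two_tailed))
  # identical distributions: t near zero
  null <- posthoc_stimulus_tests(rep(0.5, 106), rep(0.5, 106) + 1e-9 *
                                   rnorm(106), stim)
  expect_true(all(abs(null$t) < 1))
  expect_error(posthoc_stimulus_tests(item, assoc,
                                      rep("words", 106)), "condition")
})

test_that("Bonferroni adjustment multiplies, caps and sets thresholds", {
  expect_equal(bonferroni(0.001, m = 18), 0.018)
  expect_equal(bonferroni(0.2, m = 18), 1)
  expect_equal(bonferroni(c(0.001, 0.2), m = 18), c(0.018, 1))
  expect_equal(round(bonferroni_threshold(0.05, 18), 4), 0.0028)
  expect_equal(round(bonferroni_threshold(0.05, 3), 4), 0.0167)
  expect_error(bonferroni(c(0.1, 0.2), m = 1), "family")
  expect_error(bonferroni(1.2, m = 2), "0, 1")
})

test_that("the age t table flags the variables the generator separates", {
  syn <- default_cohort(1L)
  tab <- age_t_table(syn$cohort)
  expect_equal(nrow(tab), 18L)
  expect_identical(tab$variable, canonical_columns())
  expect_true(all(tab$df == 104))
  # recognition performance carries no age signal by construction
  perf <- tab[tab$variable %in% c("performance_item", "performance_assoc"), ]
  expect_true(all(!perf$significant))
})
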