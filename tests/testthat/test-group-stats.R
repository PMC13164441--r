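test_that("pooled t: identical groups, published-summary check, oracle agreement", {
  x <- c(1, 2, 3, 4, 5)
  r0 <- pooled_t(x, x)
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  # published cohort summary rows: (27, 5.16, 1.17) vs (18, 3.94, 0.46)
  r <- pooled_t(group_summary(27, 5.16, 1.17), group_summary(18, 3.94, 0.46))
  expect_equal(r$t, 4.1998, tolerance = 1e-4)   # closed form on rounded summaries
  expect_equal(r$df, 43)
  expect_equal(r$mean_difference, 1.22)
  # raw-vector path matches the brute-force formula and stats::t.test
  set.seed(8)
  for (i in 1:10) {
    a <- rnorm(sample(5:30, 1), 1, 2); b <- rnorm(sample(5:30, 1))
    rt <- pooled_t(a, b)
    expect_equal(rt$t, oracle_pooled_t(a, b), tolerance = 1e-12)
    tt <- t.test(a, b, var.equal = TRUE)
    expect_equal(rt$t, unname(tt$statistic), tolerance = 1e-10)
    expect_equal(rt$p, tt$p.value, tolerance = 1e-10)
  }
  # summary and raw entry points agree exactly
  a <- rnorm(12); b <- rnorm(9)
  expect_equal(pooled_t(a, b)$t,
               pooled_t(group_summary(12, mean(a), sd(a)),
                        group_summary(9, mean(b), sd(b)))$t, tolerance = 1e-12)
  expect_error(pooled_t(c(1, 1, 1), c(2, 2, 2)), "degenerate")
})

test_that("one-way ANOVA: F = t^2 for two groups, oracle and lm agreement", {
  set.seed(9)
  for (i in 1:100) {
    a <- rnorm(sample(4:20, 1), runif(1, -2, 2)); b <- rnorm(sample(4:20, 1))
    expect_equal(oneway_anova(list(a, b))$F, pooled_t(a, b)$t^2,
                 tolerance = 1e-9)
  }
  g <- list(rnorm(8), rnorm(6, 1), rnorm(7, 2))
  av <- oneway_anova(g)
  expect_equal(av$F, oracle_anova_F(g), tolerance = 1e-12)
  fit <- anova(lm(y ~ f, data.frame(y = unlist(g),
                                    f = factor(rep(1:3, lengths(g))))))
  expect_equal(av$F, fit$`F value`[1], tolerance = 1e-10)
  expect_equal(av$p, fit$`Pr(>F)`[1], tolerance = 1e-10)
  x <- c(2, 3, 4)
  expect_equal(oneway_anova(list(x, x, x))$F, 0)
  expect_error(oneway_anova(list(rnorm(5))), "2 groups")
})

test_that("Cohen's d: zero, antisymmetry, published-summary value", {
  a <- group_summary(10, 3, 1); b <- group_summary(12, 3, 2)
  expect_equal(cohens_d(a, b), 0)
  expect_equal(cohens_d(group_summary(27, 5.16, 1.17), group_summary(18, 3.94, 0.46)),
               1.2780, tolerance = 1e-4)
  x <- rnorm(15); y <- rnorm(20, 1)
  expect_equal(cohens_d(x, y), -cohens_d(y, x), tolerance = 1e-12)
})

test_that("Bonferroni: worked examples, capping, monotonicity, validation", {
  expect_equal(bonferroni(0.01, m = 4), 0.04)
  expect_equal(bonferroni(0.5, m = 4), 1)
  p <- runif(4)
  expect_true(all(bonferroni(p) >= p))
  expect_true(all(bonferroni(p) <= 1))
  expect_error(bonferroni(c(0.1, 0.2), m = 1), "m")
  expect_error(bonferroni(1.2), "\\[0, 1\\]")
})

test_that("bootstrap CI: degenerate inputs, determinism, sensible interval", {
  r <- bootstrap_ci(rep(3, 10), rep(3, 8), seed = 4)
  expect_equal(c(r$low, r$high), c(0, 0))
  set.seed(77); x <- rnorm(40, 2); y <- rnorm(35)
  r1 <- bootstrap_ci(x, y, seed = 123)
  r2 <- bootstrap_ci(x, y, seed = 123)
  expect_identical(r1[c("low", "high")], r2[c("low", "high")])
  expect_lt(r1$low, r1$high)
  expect_true(r1$low < mean(x) - mean(y) & mean(x) - mean(y) < r1$high)
  # custom statistic path agrees in distribution with the fast path
  r3 <- bootstrap_ci(x, y, statistic = function(a, b) mean(a) - mean(b),
                     n_boot = 500, seed = 5)
  expect_lt(abs(r3$low - r1$low), 0.5)
  expect_error(bootstrap_ci(numeric(0), y, seed = 1), "empty")
  expect_error(bootstrap_ci(x, y), "seed")
})

test_that("repeated-measures ANOVA: paired-t identity, power, unbalance error", {
  set.seed(14)
  # two time points: F equals the squared paired t statistic
  m2 <- cbind(rnorm(12), rnorm(12, 0.5))
  r <- rm_anova(m2)
  pt2 <- t.test(m2[, 1], m2[, 2], paired = TRUE)$statistic^2
  expect_equal(r$F, unname(pt2), tolerance = 1e-9)
  # strong injected time trend
  m3 <- sapply(c(0, 2, 4), function(d) rnorm(10, d, 0.5))
  expect_lt(rm_anova(m3)$p, 0.001)
  # trajectory input with a missing anchor errors naming the subject
  rows <- rbind(fake_rows("S1", "cortical", c(0, 60, 120), c(25, 26, 27), 30),
                fake_rows("S2", "cortical", c(0, 60, 120), c(24, 25, 26), 30),
                fake_rows("S3", "cortical", c(0, 160, 200), c(24, 25, 26), 30))
  expect_error(rm_anova(rows, "mean_hu", anchors = c(0, 60, 120)), "S3")
})

test_that("repeated-measures ANOVA is correctly sized under a flat null", {
  set.seed(31)
  ps <- replicate(200, rm_anova(matrix(rnorm(8 * 3), 8, 3))$p)
  # p should be uniform: check the rejection rate and the mean
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.05)
  expect_lt(abs(mean(ps) - 0.5), 0.08)
})

test_that("cohort comparison table mirrors the published layout", {
  set.seed(6)
  rows <- do.call(rbind, c(
    lapply(1:10, function(i) {
      d <- fake_rows(sprintf("C%02d", i), "cortical", c(0, 80), 26, 39,
                     lesion_sd = 5.2 + rnorm(1, 0, 1),
                     lesion_entropy = 4.3 + rnorm(1, 0, 0.3))
      d$skewness <- rnorm(1, 0, 0.2); d$kurtosis_excess <- rnorm(1, 0, 0.4); d
    }),
    lapply(1:8, function(i) {
      d <- fake_rows(sprintf("B%02d", i), "bg", c(0, 80), 26, 29,
                     lesion_sd = 3.9 + rnorm(1, 0, 0.4),
                     lesion_entropy = 4.0 + rnorm(1, 0, 0.15))
      d$skewness <- rnorm(1, 0, 0.2); d$kurtosis_excess <- rnorm(1, 0, 0.4); d
    })))
  cmp <- compare_cohort(rows, n_boot = 200, seed = 3)
  expect_equal(cmp$metric, c("sd", "skewness", "kurtosis_excess", "entropy_bits"))
  expect_true(all(cmp$p_adjusted >= cmp$p_raw))
  expect_equal(cmp$F, cmp$t^2, tolerance = 1e-9)
  expect_equal(cmp$mean_difference, cmp$mean_cortical - cmp$mean_bg, tolerance = 1e-12)
  expect_true(all(cmp$ci_low <= cmp$ci_high))
})
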