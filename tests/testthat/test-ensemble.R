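test_that("weights are -log10(p), normalized, with p = 1 giving zero weight", {
  expect_equal(compute_weights(c(0.1, 0.1)), c(0.5, 0.5))
  expect_equal(compute_weights(0.03, normalize = FALSE), -log10(0.03))
  expect_equal(compute_weights(0.03, normalize = FALSE), 1.5229, tolerance = 1e-4)
  expect_equal(compute_weights(c(1.0, 0.1)), c(0, 1))
  expect_error(compute_weights(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(compute_weights(c(0.5, 1.2)), "\\(0, 1\\]")
  expect_warning(w <- compute_weights(c(1, 1, 1)), "uniform")
  expect_equal(w, rep(1 / 3, 3))
})

test_that("weighted mean reduces to the arithmetic mean under uniform weights", {
  v <- c(0.2, 0.7, 0.1, 0.4)
  expect_equal(weighted_mean_info(v, rep(0.25, 4)), mean(v))
  expect_equal(weighted_mean_info(c(0, 1), c(0.25, 0.75)), 0.75)
  expect_equal(weighted_mean_info(0.3, 1), 0.3)
  expect_error(weighted_mean_info(c(1, 2), c(1)), "equal length")
  expect_error(weighted_mean_info(c(1, 2), c(0.3, 0.3)), "sum to 1")
})

test_that("weighted SEM scales the sample SD by the root sum of squared weights", {
  v <- c(0.1, 0.5, 0.9, 0.3, 0.6)
  expect_equal(weighted_sem_info(v, rep(0.2, 5)), stats::sd(v) / sqrt(5))
  expect_equal(weighted_sem_info(c(0.4, 0.4, 0.4), rep(1 / 3, 3)), 0)
  expect_equal(weighted_sem_info(c(0, 1, 2), c(0.2, 0.3, 0.5)),
               1 * sqrt(0.04 + 0.09 + 0.25))
  expect_error(weighted_sem_info(1, 1), "at least 2")
})

test_that("both weighted SD conventions match their closed forms", {
  expect_equal(weighted_sd_info(c(0, 1), c(0.5, 0.5)), sqrt(2 * 0.25^2))
  expect_equal(weighted_sd_info(c(0, 1), c(0.5, 0.5), "weighted-variance"), 0.5)
  expect_equal(weighted_sd_info(c(0.3, 0.3), c(0.5, 0.5)), 0)
  expect_equal(weighted_sd_info(c(0.3, 0.3), c(0.5, 0.5), "weighted-variance"), 0)
  # single dominant weight: weighted mean sits on the dominant value
  expect_equal(weighted_sd_info(c(0.8, 0.1, 0.2), c(1, 0, 0)), 0)
})

test_that("ensembles validate their inputs and recompute consistent p-values", {
  nulls <- matrix(stats::runif(30, 0, 0.1), nrow = 3)
  ens <- info_ensemble(c(0.05, 0.2, 0.01), nulls)
  expect_s3_class(ens, "info_ensemble")
  expect_equal(ens$p_values,
               vapply(1:3, function(i) mc_pvalue(ens$values[i], nulls[i, ]),
                      numeric(1)))
  expect_equal(sum(ens$weights), 1, tolerance = 1e-12)
  expect_error(info_ensemble(c(0.1, 0.2), list(c(0.1))), "one entry per source")
  expect_error(info_ensemble(c(0.1, 0.2), nulls[1:2, ], p_values = c(0, 0.5)),
               "floored")
})

test_that("KS against pooled null has the right extremes", {
  set.seed(17)
  nulls <- matrix(stats::runif(4000), nrow = 40)
  # observed values resampled from the pooled null: same distribution
  same <- info_ensemble(sample(as.vector(nulls), 40), nulls)
  ks_same <- ks_vs_null(same)
  expect_lt(ks_same$statistic, 0.25)
  expect_gt(ks_same$p_value, 0.05)
  # all observed values above every null: disjoint supports
  apart <- suppressWarnings(info_ensemble(stats::runif(40, 2, 3), nulls))
  ks_apart <- ks_vs_null(apart)
  expect_equal(ks_apart$statistic, 1)
  expect_lt(ks_apart$p_value, 1e-10)
})

test_that("the two-sided KS test detects suppressed information", {
  set.seed(23)
  nulls <- matrix(stats::runif(4000, 0, 0.2), nrow = 40)
  below <- suppressWarnings(info_ensemble(rep(0, 40), nulls))
  ks <- ks_vs_null(below)
  expect_lt(ks$p_value, 1e-6)
})

test_that("low-noise model ensembles separate sharply from their null", {
  ps <- vapply(1:20, function(i) {
    ens <- simulate_ensemble(40, s = 0.4, a = 0.1, nobs = 60, n_mc = 100,
                             seed = 800 + i)
    ks_vs_null(ens)$p_value
  }, numeric(1))
  expect_gte(mean(ps < 0.01), 0.9)
})

test_that("ensemble summaries are deterministic and fully-null ensembles stay summarizable", {
  s1 <- summary(simulate_ensemble(20, 0.4, 0.2, 60, n_mc = 50, seed = 5))
  s2 <- summary(simulate_ensemble(20, 0.4, 0.2, 60, n_mc = 50, seed = 5))
  expect_identical(s1, s2)
  null_ens <- suppressWarnings(
    simulate_ensemble(40, s = 0, a = 1, nobs = 60, n_mc = 100, seed = 31))
  sm <- suppressWarnings(summary(null_ens))
  # finite observations make even pure-noise MI strictly positive on average
  expect_gt(sm$weighted_mean, 0)
  expect_gte(sm$weighted_sem, 0)
  expect_gte(sm$weighted_sd, 0)
})

test_that("coef and weights methods expose the weighted mean and normalized weights", {
  ens <- simulate_ensemble(10, 0.5, 0.2, 60, n_mc = 50, seed = 77)
  expect_equal(unname(coef(ens)), weighted_mean_info(ens$values, ens$weights))
  expect_equal(sum(weights(ens)), 1, tolerance = 1e-12)
  expect_equal(weights(ens), compute_weights(ens$p_values))
})

test_that("comparing an ensemble against itself gives zero difference and maximal p", {
  ens <- simulate_ensemble(20, 0.4, 0.3, 60, n_mc = 50, seed = 19)
  cmp <- compare_ensembles(ens, ens, n_perm = 200, seed = 20)
  expect_identical(cmp$observed_difference, 0)
  expect_identical(cmp$p_value, 1)
  expect_identical(cmp$direction, "equal")
})

test_that("the comparison is antisymmetric in its arguments", {
  a <- simulate_ensemble(20, 0.6, 0.3, 60, n_mc = 50, seed = 21)
  b <- simulate_ensemble(20, 0.2, 0.3, 60, n_mc = 50, seed = 22)
  ab <- compare_ensembles(a, b, n_perm = 500, seed = 23)
  ba <- compare_ensembles(b, a, n_perm = 500, seed = 23)
  expect_equal(ab$observed_difference, -ba$observed_difference)
  # equal group sizes: the permutation null is symmetric, mirrored tails match
  expect_equal(ab$p_value, ba$p_value, tolerance = 0.05)
  expect_identical(ab$direction, "A > B")
  expect_identical(ba$direction, "B > A")
})

test_that("permutations preserve the pooled values and group sizes", {
  a <- simulate_ensemble(8, 0.6, 0.3, 60, n_mc = 20, seed = 31)
  b <- simulate_ensemble(12, 0.2, 0.3, 60, n_mc = 20, seed = 32)
  cmp <- compare_ensembles(a, b, n_perm = 300, seed = 33)
  expect_length(cmp$perm_differences, 300)
  # every permuted difference must be attainable from the pooled values:
  # bounded by the range spanned by the pooled information values
  pool <- c(a$values, b$values)
  expect_true(all(cmp$perm_differences >= min(pool) - max(pool)))
  expect_true(all(cmp$perm_differences <= max(pool) - min(pool)))
})

test_that("exchangeable ensembles give uniform-ish two-sided comparison p-values", {
  ps <- vapply(1:40, function(i) {
    a <- simulate_ensemble(20, 0.4, 0.5, 60, n_mc = 30, seed = 2000 + 2 * i)
    b <- simulate_ensemble(20, 0.4, 0.5, 60, n_mc = 30, seed = 2001 + 2 * i)
    compare_ensembles(a, b, n_perm = 100, seed = 3000 + i,
                      alternative = "two.sided")$p_value
  }, numeric(1))
  expect_gt(mean(ps), 0.3)
  expect_lt(mean(ps), 0.7)
})

test_that("widely separated ensembles reach the permutation floor", {
  a <- simulate_ensemble(40, 0.9, 0.1, 60, n_mc = 30, seed = 41)
  b <- simulate_ensemble(40, 0.05, 0.1, 60, n_mc = 30, seed = 42)
  cmp <- compare_ensembles(a, b, n_perm = 1000, seed = 43)
  expect_identical(cmp$p_value, 0.0005)
})
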