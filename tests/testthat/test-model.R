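test_that("count table matches the closed form at the corner cases", {
  expect_equal(as.vector(count_table(8, 0)), rep(2L, 4))
  expect_equal(unname(count_table(8, 1)), matrix(c(4L, 0L, 0L, 4L), 2))
  expect_equal(unname(count_table(60, 0.4)), matrix(c(21L, 9L, 9L, 21L), 2))
})

test_that("rounding in the count table is half-up, not half-even", {
  # 60 * 0.1 / 4 = 1.5 -> 2 under half-up (base::round would give 2 here too,
  # but 4 * 0.5 / 4 = 0.5 -> 1 separates the conventions: round(0.5) == 0)
  expect_equal(unname(diag(count_table(60, 0.1))), c(17L, 17L))
  expect_equal(unname(count_table(4, 0.5)), matrix(c(2L, 0L, 0L, 2L), 2))
  expect_equal(unname(count_table(4, 0.2)), matrix(c(1L, 1L, 1L, 1L), 2))
})

test_that("count table cells sum to nobs, stay non-negative, and the diagonal is monotone in s", {
  s_grid <- seq(0, 1, by = 0.05)
  for (nobs in c(4, 8, 20, 60, 100)) {
    tabs <- lapply(s_grid, function(s) count_table(nobs, s))
    expect_true(all(vapply(tabs, sum, numeric(1)) == nobs))
    expect_true(all(vapply(tabs, min, numeric(1)) >= 0))
    diag1 <- vapply(tabs, function(t) t[1, 1], numeric(1))
    expect_true(all(diff(diag1) >= 0))
    # balanced marginals
    expect_true(all(vapply(tabs, function(t)
      all(rowSums(t) == nobs / 2, colSums(t) == nobs / 2), logical(1))))
  }
})

test_that("invalid model parameters are rejected", {
  expect_error(count_table(8, -0.1), "in \\[0, 1\\]")
  expect_error(count_table(8, 1.1), "in \\[0, 1\\]")
  expect_error(count_table(2, 0.5), ">= 4")
  expect_error(count_table(10, 0.5), "multiple of 4")
  expect_error(simulate_observations(60, 0.5, a = 2), "in \\[0, 1\\]")
})

test_that("non-multiple-of-4 counts are allowed with the permissive flag", {
  for (nobs in c(5, 7, 13, 61)) {
    tab <- count_table(nobs, 0.3, allow_any_nobs = TRUE)
    expect_equal(sum(tab), nobs)
    expect_true(min(tab) >= 0)
    # deterministic remainder placement
    expect_identical(tab, count_table(nobs, 0.3, allow_any_nobs = TRUE))
  }
  obs <- simulate_observations(13, 0.3, 0.2, seed = 9, allow_any_nobs = TRUE)
  expect_length(obs$x, 13)
})

test_that("deterministic observations at a = 0 reproduce the count table", {
  obs <- simulate_observations(8, s = 1, a = 0, seed = 1)
  expect_true(all(obs$x == obs$y))
  obs0 <- simulate_observations(8, s = 0, a = 0, seed = 1)
  counts <- table(obs0$x, obs0$y)
  expect_true(all(counts == 2))
  # realized joint counts always match the expected table before noise
  for (s in c(0.2, 0.5, 0.9)) {
    obs <- simulate_observations(60, s = s, a = 0, seed = 42)
    expect_equal(unname(as.matrix(table(obs$y, obs$x))),
                 matrix(as.vector(count_table(60, s)), 2))
  }
})

test_that("simulation is reproducible under a seed and leaves the global RNG alone", {
  o1 <- simulate_observations(100, 0.5, 0.3, seed = 7)
  o2 <- simulate_observations(100, 0.5, 0.3, seed = 7)
  expect_identical(o1, o2)
  set.seed(123)
  before <- .Random.seed
  invisible(simulate_observations(60, 0.4, 0.5, seed = 11))
  expect_identical(.Random.seed, before)
})

test_that("noise preserves x, the y multiset, and both marginals", {
  obs <- simulate_observations(60, s = 0.8, a = 0, seed = 3)
  same <- apply_noise(obs, 0, seed = 5)
  expect_identical(same, obs)
  for (seed in 1:20) {
    for (a in c(0.25, 0.5, 1)) {
      noisy <- apply_noise(obs, a, seed = seed)
      expect_identical(noisy$x, obs$x)
      expect_equal(sort(noisy$y), sort(obs$y))
      expect_equal(sum(noisy$y), 30)
      # no more than Round(nobs * a) positions can change
      expect_lte(sum(noisy$y != obs$y), floor(60 * a + 0.5))
    }
  }
})

test_that("full noise erases the interaction strength", {
  # MI distribution of (s = 0.8, a = 1) models matches that of (s = 0, a = 1)
  mi_high_s <- vapply(1:300, function(i)
    mutual_information(simulate_observations(60, 0.8, 1, seed = 100 + i)),
    numeric(1))
  mi_zero_s <- vapply(1:300, function(i)
    mutual_information(simulate_observations(60, 0, 1, seed = 7000 + i)),
    numeric(1))
  ks <- suppressWarnings(stats::ks.test(mi_high_s, mi_zero_s))
  expect_gt(ks$p.value, 0.01)
})
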