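test_that("wasserstein_1d reproduces closed-form cases", {
  expect_equal(wasserstein_1d(5, 12), 7)
  expect_equal(wasserstein_1d(c(3, 3, 10), c(3, 3, 10)), 0)
  # equal-size closed form: mean |sorted differences|
  expect_equal(wasserstein_1d(c(0, 4), c(1, 3)), 1)
  # unequal sizes, fixed via the transport oracle: masses (1/2,1/2) vs
  # (1/3,1/3,1/3) on {0,10} vs {5,5,5}
  expect_equal(wasserstein_1d(c(0, 10), c(5, 5, 5)), 5)
  expect_error(wasserstein_1d(numeric(0), 1), "non-empty")
  expect_error(wasserstein_1d(c(1, NA), 1), "finite")
})

test_that("wasserstein_1d matches the quantile-function oracle on random instances", {
  set.seed(101)
  for (i in 1:200) {
    a <- runif(sample(1:8, 1), -50, 50)
    b <- runif(sample(1:8, 1), -50, 50)
    expect_equal(wasserstein_1d(a, b), oracle_w1_quantile(a, b),
                 tolerance = 1e-12)
  }
})

test_that("wasserstein_1d is a metric with translation equivariance", {
  set.seed(7)
  for (i in 1:50) {
    a <- rnorm(sample(2:20, 1), sd = 10)
    b <- rnorm(sample(2:20, 1), sd = 10)
    cc <- rnorm(sample(2:20, 1), sd = 10)
    dab <- wasserstein_1d(a, b)
    expect_equal(dab, wasserstein_1d(b, a))
    expect_lte(dab, wasserstein_1d(a, cc) + wasserstein_1d(cc, b) + 1e-10)
    # common shift leaves the distance unchanged
    expect_equal(wasserstein_1d(a + 3.7, b + 3.7), dab, tolerance = 1e-10)
  }
  # shifting one equal-shape sample by delta gives |delta|
  x <- rnorm(40, 50, 12)
  expect_equal(wasserstein_1d(x, x + 25), 25, tolerance = 1e-10)
  expect_equal(wasserstein_1d(x, x - 4.2), 4.2, tolerance = 1e-10)
})

test_that("permutation p-values obey the add-one bounds", {
  # identical samples: observed 0, every permuted distance >= 0 ties in
  expect_equal(permutation_test(1:3, 1:3, n_perm = 999, seed = 3)$p_value, 1)
  # two well-separated point masses: the observed distance is attained by
  # essentially no random re-partition, so p hits the floor 1/(n_perm+1)
  res <- permutation_test(rep(0, 15), rep(1000, 15), n_perm = 999, seed = 5)
  expect_equal(res$p_value, 0.001)
  expect_gte(res$p_value, 1 / (res$n_perm + 1))
  expect_error(permutation_test(1:3, 1:3, n_perm = 0, seed = 1), "n_perm")
  expect_error(permutation_test(1:3, 1:3, n_perm = 99), "seed")
})

test_that("permutation tests are reproducible and label-symmetric", {
  set.seed(1234)
  a <- rnorm(20, 10, 4); b <- rnorm(25, 12, 4)
  r1 <- permutation_test(a, b, n_perm = 199, seed = 42)
  r2 <- permutation_test(a, b, n_perm = 199, seed = 42)
  expect_identical(r1$p_value, r2$p_value)
  expect_identical(r1$max_perm_distance, r2$max_perm_distance)
  r3 <- permutation_test(a, b, n_perm = 199, seed = 43)
  expect_false(identical(r1$max_perm_distance, r3$max_perm_distance))
  # observed statistic is symmetric in the labels
  expect_equal(r1$observed_distance,
               permutation_test(b, a, n_perm = 1, seed = 1)$observed_distance)
  # the session RNG stream is not consumed
  set.seed(99); x1 <- runif(1)
  set.seed(99); invisible(permutation_test(a, b, n_perm = 9, seed = 1))
  expect_identical(runif(1), x1)
})

test_that("gene_seed is deterministic and spreads over genes", {
  expect_identical(gene_seed(1, "GENE0001"), gene_seed(1, "GENE0001"))
  s <- vapply(sprintf("GENE%04d", 1:500), function(g) gene_seed(7, g), 1L)
  expect_equal(length(unique(s)), 500L)
  expect_true(all(s >= 0 & s < 2^31))
})

test_that("bh_fdr implements the step-up rule", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(11)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-12)
    expect_true(all(bh_fdr(p) >= p))
  }
  expect_error(bh_fdr(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_fdr(1.2), "\\(0, 1\\]")
})

test_that("fisher_2x2 reports the sample odds ratio and the exact p", {
  r <- fisher_2x2(matrix(c(10, 10, 10, 10), 2, byrow = TRUE))
  expect_equal(r$odds_ratio, 1)
  expect_equal(r$p_value, 1)
  expect_equal(fisher_2x2(c(0, 5, 5, 0))$odds_ratio, 0)
  expect_equal(fisher_2x2(c(5, 0, 0, 5))$odds_ratio, Inf)
  expect_true(is.nan(fisher_2x2(c(0, 5, 0, 5))$odds_ratio))
  expect_error(fisher_2x2(c(-1, 2, 3, 4)), "non-negative")
  expect_error(fisher_2x2(c(0, 0, 0, 0)), "positive")
})

test_that("fisher_2x2 p matches brute-force hypergeometric enumeration", {
  tabs <- list(
    matrix(c(1, 9, 11, 3), 2, byrow = TRUE),
    matrix(c(4, 16, 40, 60), 2, byrow = TRUE),
    matrix(c(0, 10, 5, 25), 2, byrow = TRUE)
  )
  set.seed(21)
  for (i in 1:10)
    tabs[[length(tabs) + 1L]] <-
      matrix(rpois(4, lambda = sample(3:30, 1)), 2)
  for (tab in tabs) {
    if (sum(tab) == 0) next
    expect_equal(fisher_2x2(tab)$p_value, oracle_fisher_p(tab),
                 tolerance = 1e-10)
  }
})
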