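test_that("size factors match hand-computed median-of-ratios", {
  # [[2,4],[6,12]]: geometric means (2*4)^0.5, (6*12)^0.5; ratios give
  # factors (1/sqrt(2), sqrt(2))
  m <- matrix(c(2, 6, 4, 12), nrow = 2)
  expect_equal(size_factors(m), c(1 / sqrt(2), sqrt(2)))
  # identical columns -> equal factors
  m2 <- matrix(c(5, 9, 13, 5, 9, 13), nrow = 3)
  sf <- size_factors(m2)
  expect_equal(sf[1], sf[2])
  # column scaled by 3 -> factor ratio exactly 3
  m3 <- cbind(a = c(5, 9, 13), b = 3 * c(5, 9, 13))
  sf <- size_factors(m3)
  expect_equal(sf[["b"]] / sf[["a"]], 3)
  expect_error(size_factors(matrix(c(0, 1, 1, 0), 2)), "all-positive")
})

test_that("size factors are column-scale equivariant", {
  # scaling one column by c multiplies its factor by c relative to the
  # others (the geometric-mean reference absorbs a common c^(1/n))
  set.seed(41)
  for (i in 1:20) {
    m <- matrix(rpois(60, 50) + 1, nrow = 10)
    sf <- size_factors(m)
    j <- sample(6, 1)
    c_ <- runif(1, 0.2, 5)
    m2 <- m
    m2[, j] <- m[, j] * c_
    sf2 <- size_factors(m2)
    expect_equal(sf2[j] / sf2[-j], c_ * sf[j] / sf[-j], tolerance = 1e-12)
  }
})

test_that("size factors agree with the reference median-of-ratios routine", {
  skip_if_not_installed("DESeq2")
  set.seed(42)
  # odd row count: the median picks one ratio exactly in both routines
  m <- matrix(rnbinom(606, mu = 100, size = 5) + 1, nrow = 101)
  expect_equal(unname(size_factors(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)))
})

test_that("moment dispersion estimates recover the simulation truth", {
  groups <- function(n) factor(rep(c("A", "B"), each = n))
  # Poisson counts at large n: estimates collapse toward the floor
  set.seed(51)
  m <- matrix(rpois(200 * 200, 100), nrow = 200)
  a <- estimate_dispersion(m, groups(100), sf = rep(1, 200))
  expect_lt(median(a), 0.01)
  # NB alpha = 0.2 at n = 50 per group
  m <- matrix(rnbinom(200 * 100, mu = 200, size = 1 / 0.2), nrow = 200)
  a <- estimate_dispersion(m, groups(50), sf = rep(1, 100))
  expect_gt(median(a), 0.1)
  expect_lt(median(a), 0.3)
  # constant counts -> floor
  m <- matrix(7, nrow = 2, ncol = 8)
  expect_equal(estimate_dispersion(m, groups(4), sf = rep(1, 8)),
               rep(1e-8, 2))
  expect_error(estimate_dispersion(m, factor(c("A", rep("B", 7)))), "two samples")
})

test_that("exact test matches hand-derived limits", {
  # symmetric observed split at equal means is the mode -> p = 1
  expect_equal(nb_exact_test(3, 3, 3, 3, alpha = 0.1), 1)
  # alpha -> 0, equal means, K = 4, observed (0, 4): binomial(4, 1/2)
  # two-sided enumeration P{0 or 4} = 2/16
  expect_equal(nb_exact_test(0, 4, 2, 2, alpha = 0), 0.125)
  # K = 0 convention
  expect_equal(nb_exact_test(0, 0, 1, 1, alpha = 0.1), 1)
  expect_error(nb_exact_test(-1, 3, 1, 1, 0.1), ">= 0")
})

test_that("exact test equals brute-force enumeration on random instances", {
  set.seed(61)
  for (i in 1:200) {
    K <- sample(1:50, 1)
    ka <- sample(0:K, 1)
    mu <- runif(2, 0.5, 30)
    alpha <- sample(c(0, runif(1, 0, 1)), 1)
    n_a <- sample(1:8, 1)
    n_b <- sample(1:8, 1)
    p <- nb_exact_test(ka, K - ka, mu[1], mu[2], alpha, n_a, n_b)
    p0 <- brute_nb_exact(ka, K - ka, mu[1], mu[2], alpha, n_a, n_b)
    expect_lt(abs(p - p0) / p0, 1e-12)
  }
})

test_that("windowed enumeration agrees with full enumeration at large totals", {
  # totals above the full-enumeration cutoff use a mass window; compare
  # against direct summation over the whole support
  for (ka in c(40000, 60000, 75000)) {
    kb <- 120000 - ka
    p <- nb_exact_test(ka, kb, 6e4, 6e4, alpha = 0.01, n_a = 5, n_b = 5)
    p0 <- brute_nb_exact(ka, kb, 6e4, 6e4, alpha = 0.01, n_a = 5, n_b = 5)
    expect_equal(p, p0, tolerance = 1e-10)
  }
})

test_that("BH adjustment follows the step-up definition", {
  expect_equal(adjust_bh(0.03), 0.03)
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(71)
  p <- runif(100)
  padj <- adjust_bh(p)
  expect_true(all(padj >= p - 1e-15))
  expect_true(all(padj <= 1))
  # monotone in p-rank
  o <- order(p)
  expect_true(all(diff(padj[o]) >= -1e-15))
})

test_that("differential expression recovers planted fold changes", {
  set.seed(81)
  n <- 5
  mu <- 200
  planted <- 1:20
  m <- matrix(rnbinom(100 * 2 * n, mu = mu, size = 1 / 0.05), nrow = 100)
  m[planted, (n + 1):(2 * n)] <-
    rnbinom(length(planted) * n, mu = 4 * mu, size = 1 / 0.05)
  groups <- factor(rep(c("A", "B"), each = n))
  de <- differential_expression(m, groups)
  expect_lt(abs(median(de$log2FC[planted]) - 2), 0.3)
  expect_true(all(de$padj >= de$pvalue - 1e-15))
})

test_that("all-zero rows and row permutations are handled coherently", {
  set.seed(82)
  m <- matrix(rnbinom(80, mu = 50, size = 10) + 1, nrow = 8)
  m[3, ] <- 0
  rownames(m) <- sprintf("m%d", 1:8)
  groups <- factor(rep(c("A", "B"), each = 5))
  de <- differential_expression(m, groups)
  expect_equal(de$pvalue[3], 1)
  expect_equal(de$log2FC[3], 0)
  # row permutation permutes results without changing them
  perm <- sample(8)
  de2 <- differential_expression(m[perm, ], groups)
  expect_equal(de2[match(de$mirna_id, de2$mirna_id), -1], de[, -1],
               ignore_attr = TRUE)
})

test_that("exact test is calibrated when the dispersion is known", {
  # diagnostic for the null behavior of the test itself, separate from
  # dispersion-estimation noise: with the true alpha supplied, the
  # fraction of p < 0.05 sits at the nominal level
  set.seed(91)
  n <- 5
  alpha <- 0.05
  p <- replicate(2000, {
    ka <- sum(rnbinom(n, mu = 200, size = 1 / alpha))
    kb <- sum(rnbinom(n, mu = 200, size = 1 / alpha))
    q <- (ka + kb) / (2 * n)
    nb_exact_test(ka, kb, n * q, n * q, alpha, n, n)
  })
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.015)
})
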