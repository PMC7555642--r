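## Statistical primitives against closed forms and independent oracles.

test_that("chi-square 2x2 matches closed forms and the classical O-E sum", {
  expect_equal(chi_square_2x2(10, 0, 0, 10)$statistic, 20)
  expect_equal(chi_square_2x2(54, 6, 18, 42)$statistic, 45)
  r <- chi_square_2x2(5, 5, 5, 5)
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  expect_error(chi_square_2x2(0, 0, 3, 4), "marginal")

  ## oracle: sum over cells of (O - E)^2 / E, and base R chisq.test
  oe_sum <- function(a, b, c, d) {
    o <- matrix(c(a, b, c, d), 2, byrow = TRUE)
    e <- outer(rowSums(o), colSums(o)) / sum(o)
    sum((o - e)^2 / e)
  }
  set.seed(1)
  for (i in 1:1000) {
    t <- rpois(4, sample(c(3, 20, 200), 1)) + 1
    got <- chi_square_2x2(t[1], t[2], t[3], t[4])
    expect_equal(got$statistic, oe_sum(t[1], t[2], t[3], t[4]),
                 tolerance = 1e-9)
    ref <- suppressWarnings(
      stats::chisq.test(matrix(t, 2, byrow = TRUE), correct = FALSE))
    expect_equal(got$p, unname(ref$p.value), tolerance = 1e-12)
  }
  ## large counts must not overflow
  big <- chi_square_2x2(500000, 400000, 480000, 430000)
  expect_true(is.finite(big$statistic) && big$statistic > 0)
})

test_that("BH adjustment reproduces the textbook step-up rule", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.5), 0.5)
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(2)
  p <- runif(20)
  o <- sample(20)
  expect_equal(bh_fdr(p)[o], bh_fdr(p[o]))  # permutation equivariance

  step_up_rejections <- function(p, t) {
    m <- length(p)
    s <- sort(p)
    k <- suppressWarnings(max(which(s <= t * seq_len(m) / m)))
    if (!is.finite(k)) return(integer(0))
    which(p <= s[k])
  }
  for (i in 1:1000) {
    m <- sample(1:40, 1)
    p <- round(runif(m), 3)
    t <- runif(1, 0.01, 0.2)
    q <- bh_fdr(p)
    expect_equal(which(q <= t), step_up_rejections(p, t))
    expect_equal(q, stats::p.adjust(p, "BH"))
  }
})

test_that("hypergeometric upper tail is exact", {
  expect_equal(hypergeometric_tail(4, 5, 5, 20), 76 / choose(20, 5),
               tolerance = 1e-12)
  expect_equal(hypergeometric_tail(0, 5, 5, 20), 1)
  expect_equal(hypergeometric_tail(5, 5, 5, 5), 1)
  expect_error(hypergeometric_tail(6, 5, 5, 20), "inconsistent")

  ## oracle: direct summation of choose-products, and Fisher's exact test
  enum_tail <- function(k, K, n, N) {
    j <- seq.int(k, min(K, n))
    sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
  }
  set.seed(3)
  for (i in 1:100) {
    N <- sample(5:40, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
    lo <- max(0, n + K - N); hi <- min(K, n)
    k <- if (hi > lo) sample(lo:hi, 1) else lo
    got <- hypergeometric_tail(k, K, n, N)
    expect_equal(got, enum_tail(k, K, n, N), tolerance = 1e-10)
    f <- stats::fisher.test(
      matrix(c(k, K - k, n - k, N - K - n + k), 2), alternative = "greater")
    expect_equal(got, unname(f$p.value), tolerance = 1e-8)
  }
})

test_that("wilcoxon rank-sum: exact enumeration, ties, and approximation", {
  expect_equal(wilcoxon_rank_sum(1:3, 4:6)$p, 0.1)
  expect_equal(wilcoxon_rank_sum(c(1, 2, 2), c(1, 2, 2))$p, 1)

  ## exact branch vs wilcox.test exact p on tie-free samples, all n+m <= 10
  set.seed(4)
  for (i in 1:60) {
    n <- sample(1:5, 1); m <- sample(1:5, 1)
    x <- sample(100, n); y <- setdiff(sample(100, n + m), x)[seq_len(m)]
    for (alt in c("two.sided", "greater", "less")) {
      got <- wilcoxon_rank_sum(x, y, alt)$p
      ref <- stats::wilcox.test(x, y, alternative = alt, exact = TRUE)$p.value
      expect_equal(got, unname(ref), tolerance = 1e-12)
    }
  }
  ## exact and approximate branches agree for moderate samples
  for (i in 1:20) {
    x <- rnorm(6); y <- rnorm(6)
    pe <- wilcoxon_rank_sum(x, y)$p
    pa <- wilcoxon_rank_sum(x, y, exact_limit = 0L)$p
    expect_lt(abs(pe - pa), 0.02)
  }
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")
})

test_that("spearman rho equals rank Pearson", {
  expect_equal(spearman_rho(1:3, 3:1), -1)
  expect_equal(spearman_rho(1:3, c(10, 20, 30)), 1)
  expect_equal(spearman_rho(1:4, c(1, 3, 2, 4)), 0.8)
  expect_true(is.na(spearman_rho(c(1, 1, 1), 1:3)))
  set.seed(5)
  for (i in 1:50) {
    x <- sample(10, 20, replace = TRUE); y <- rnorm(20)
    expect_equal(spearman_rho(x, y), cor(x, y, method = "spearman"),
                 tolerance = 1e-12)
  }
})

test_that("binomial survival function is exact and stable", {
  expect_equal(binomial_sf(4, 4, 0.0038), 0.0038^4, tolerance = 1e-12)
  expect_equal(binomial_sf(0, 10, 0.3), 1)
  ## pmf sums to 1: sf(k) - sf(k+1) = pmf(k)
  n <- 25; p0 <- 0.13
  sf <- binomial_sf(0:n, n, p0)
  pmf <- sf - c(sf[-1], 0)
  expect_equal(sum(pmf), 1, tolerance = 1e-12)
  set.seed(6)
  for (i in 1:100) {
    n <- sample(1:60, 1); k <- sample(0:n, 1); p0 <- runif(1, 0.001, 0.999)
    expect_equal(binomial_sf(k, n, p0),
                 stats::pbinom(k - 1, n, p0, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
  ## deep tails do not underflow to garbage
  expect_gt(binomial_sf(10, 10, 0.004), 0)
  expect_lt(binomial_sf(10, 10, 0.004), 1e-23)
  ## two-sided convention
  expect_equal(binomial_test_two_sided(5, 10, 0.5), 1)
  set.seed(7)
  for (i in 1:50) {
    n <- sample(2:40, 1); k <- sample(0:n, 1); p0 <- runif(1, 0.05, 0.95)
    lo <- stats::pbinom(k, n, p0)
    hi <- stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
    expect_equal(binomial_test_two_sided(k, n, p0), min(1, 2 * min(lo, hi)),
                 tolerance = 1e-10)
  }
})
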