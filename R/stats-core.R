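## Self-contained statistical primitives used throughout the pipeline.
## Each is written so that it can be checked against an independent oracle
## (closed form, exhaustive enumeration, or the corresponding base-R test).

#' Pearson chi-square test on a 2x2 contingency table
#'
#' Computes the uncorrected (no Yates continuity correction) Pearson
#' chi-square statistic for a 2x2 table of read counts, typically methylated
#' versus unmethylated reads in two samples pooled over a region. Uses the
#' closed form `N (ad - bc)^2 / (r1 r2 c1 c2)` and the 1-df chi-square
#' survival function for the p-value.
#'
#' @param a,b,c,d Non-negative counts; rows are samples, columns are
#'   methylated/unmethylated reads, i.e. the table is
#'   `rbind(c(a, b), c(c, d))`.
#' @return A list with `statistic` and `p`.
#' @examples
#' chi_square_2x2(10, 0, 0, 10)  # statistic 20
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  stopifnot(length(a) == 1L, a >= 0, b >= 0, c >= 0, d >= 0)
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  if (n <= 0) stop("empty contingency table")
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) {
    stop("chi-square undefined: a row or column marginal is zero")
  }
  stat <- n * (a * d - b * c)^2 / (r1 * r2 * c1 * c2)
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

## vectorised core used by the DMR caller; marginal checks done by caller
chi_square_2x2_vec <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  stat <- n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up FDR adjustment: in sorted order `q(i) = min_{j >= i} p(j) m / j`,
#' capped at 1 and mapped back to the input order. Thresholding the returned
#' q-values at `t` rejects exactly the hypotheses selected by the textbook
#' BH step-up rule at level `t`.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NA allowed, propagated).
#' @return Adjusted q-values in input order.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  pp <- p[ok]
  m <- length(pp)
  if (m > 0L) {
    o <- order(pp, decreasing = TRUE)
    ro <- order(o)
    q[ok] <- pmin(1, cummin(pp[o] * m / seq(m, 1)))[ro]
  }
  q
}

#' Upper tail of the hypergeometric distribution
#'
#' Exact `P(X >= k)` for `X ~ Hypergeometric(N, K, n)` (a study set of size
#' `n` drawn from a universe of `N` genes of which `K` carry the term),
#' summed in log space. This is the one-sided enrichment p-value.
#'
#' @param k Observed overlap (successes in the draw).
#' @param K Number of successes in the population.
#' @param n Draw (study set) size.
#' @param N Population (universe) size.
#' @return The upper-tail probability.
#' @examples
#' hypergeometric_tail(4, 5, 5, 20)  # 76 / choose(20, 5)
#' @export
hypergeometric_tail <- function(k, K, n, N) {
  stopifnot(length(k) == 1L)
  if (any(c(k, K, n, N) < 0) || K > N || n > N || k > min(K, n)) {
    stop("inconsistent hypergeometric arguments")
  }
  if (k <= max(0, n + K - N)) return(1)
  j <- seq.int(k, min(K, n))
  lt <- lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)
  mx <- max(lt)
  min(1, exp(mx + log(sum(exp(lt - mx)))))
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Rank-sum test with average ranks for ties. The p-value is exact (full
#' enumeration of all `choose(n + m, n)` assignments of the pooled ranks)
#' when `n + m <= exact_limit`, otherwise a normal approximation with tie
#' correction and continuity correction is used.
#'
#' @param x,y Numeric samples (each non-empty).
#' @param alternative One of `"two.sided"`, `"greater"`, `"less"`;
#'   `"greater"` means `x` tends to exceed `y`.
#' @param exact_limit Combined-size cutoff for the exact branch.
#' @return A list with `U` (Mann-Whitney U for `x`) and `p`.
#' @examples
#' wilcoxon_rank_sum(1:3, 4:6)$p  # 0.1
#' @export
wilcoxon_rank_sum <- function(x, y, alternative = c("two.sided", "greater", "less"),
                              exact_limit = 12L) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 1L || length(y) < 1L) stop("both samples must be non-empty")
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  rs_x <- sum(r[seq_len(n)])
  u <- rs_x - n * (n + 1) / 2

  if (n + m <= exact_limit) {
    idx <- utils::combn(n + m, n)
    all_u <- colSums(matrix(r[idx], nrow = n)) - n * (n + 1) / 2
    tol <- 1e-9
    p_ge <- mean(all_u >= u - tol)
    p_le <- mean(all_u <= u + tol)
    p <- switch(alternative,
      two.sided = min(1, 2 * min(p_ge, p_le)),
      greater   = p_ge,
      less      = p_le)
  } else {
    nties <- table(r)
    mu <- n * m / 2
    sigma2 <- (n * m / 12) *
      ((n + m + 1) - sum(nties^3 - nties) / ((n + m) * (n + m - 1)))
    if (sigma2 <= 0) return(list(U = u, p = 1))
    cc <- 0.5  # continuity correction
    z_ge <- (u - mu - cc) / sqrt(sigma2)
    z_le <- (u - mu + cc) / sqrt(sigma2)
    p_ge <- stats::pnorm(z_ge, lower.tail = FALSE)
    p_le <- stats::pnorm(z_le)
    p <- switch(alternative,
      two.sided = min(1, 2 * min(p_ge, p_le)),
      greater   = p_ge,
      less      = p_le)
  }
  list(U = u, p = p)
}

#' Spearman rank correlation
#'
#' Pearson correlation of average-tie ranks. Returns `NA` when either vector
#' is constant (undefined correlation).
#'
#' @param x,y Equal-length numeric vectors, length at least 3 after removing
#'   incomplete pairs.
#' @return The correlation `rho`, or `NA`.
#' @examples
#' spearman_rho(1:4, c(1, 3, 2, 4))  # 0.8
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) return(NA_real_)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(NA_real_)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

#' Binomial survival function
#'
#' Exact `P(X >= k)` for `X ~ Binomial(n, p0)`, summed in log space over the
#' shorter tail for numerical stability. Supports vector `k`, `n`.
#'
#' @param k Number of successes (vector allowed).
#' @param n Number of trials (vector allowed, recycled with `k`).
#' @param p0 Success probability in `(0, 1)` (scalar).
#' @return `P(X >= k)` for each element.
#' @examples
#' binomial_sf(4, 4, 0.0038)  # 0.0038^4
#' @export
binomial_sf <- function(k, n, p0) {
  if (length(p0) != 1L || p0 <= 0 || p0 >= 1) stop("p0 must be a scalar in (0, 1)")
  ln <- max(length(k), length(n))
  k <- rep_len(as.numeric(k), ln)
  n <- rep_len(as.numeric(n), ln)
  if (any(k < 0 | k > n | n < 0)) stop("need 0 <= k <= n")
  out <- numeric(ln)
  key <- paste(k, n)
  first <- !duplicated(key)
  uk <- k[first]; un <- n[first]
  uv <- vapply(seq_along(uk), function(i) .binom_sf_one(uk[i], un[i], p0), numeric(1))
  out <- uv[match(key, key[first])]
  out
}

.binom_sf_one <- function(k, n, p0) {
  if (k <= 0) return(1)
  lse <- function(lx) { mx <- max(lx); mx + log(sum(exp(lx - mx))) }
  lterm <- function(j) lchoose(n, j) + j * log(p0) + (n - j) * log1p(-p0)
  if (n - k < k) {                 # upper tail is the shorter sum
    min(1, exp(lse(lterm(seq.int(k, n)))))
  } else {                         # complement of the lower tail
    lcdf <- lse(lterm(seq.int(0, k - 1)))
    max(0, min(1, -expm1(lcdf)))
  }
}

#' Binomial cumulative distribution function
#'
#' Exact `P(X <= k)`, computed directly in log space over the shorter tail
#' (never as `1 - P(X >= k + 1)`, which loses precision for small lower
#' tails). Vectorised like [binomial_sf()].
#'
#' @inheritParams binomial_sf
#' @return `P(X <= k)` for each element.
#' @export
binomial_cdf <- function(k, n, p0) {
  if (length(p0) != 1L || p0 <= 0 || p0 >= 1) stop("p0 must be a scalar in (0, 1)")
  ln <- max(length(k), length(n))
  k <- rep_len(as.numeric(k), ln)
  n <- rep_len(as.numeric(n), ln)
  if (any(k < 0 | k > n | n < 0)) stop("need 0 <= k <= n")
  key <- paste(k, n)
  first <- !duplicated(key)
  uv <- vapply(which(first), function(i) .binom_cdf_one(k[i], n[i], p0), numeric(1))
  uv[match(key, key[first])]
}

.binom_cdf_one <- function(k, n, p0) {
  if (k >= n) return(1)
  lse <- function(lx) { mx <- max(lx); mx + log(sum(exp(lx - mx))) }
  lterm <- function(j) lchoose(n, j) + j * log(p0) + (n - j) * log1p(-p0)
  if (k + 1 <= n - k) {            # lower tail is the shorter sum
    min(1, exp(lse(lterm(seq.int(0, k)))))
  } else {                         # complement of the upper tail
    lsf <- lse(lterm(seq.int(k + 1, n)))
    max(0, min(1, -expm1(lsf)))
  }
}

#' Exact two-sided binomial test p-value
#'
#' Doubled smaller-tail convention: `min(1, 2 min(P(X <= k), P(X >= k)))`.
#' Used by the pooled-count differential expression test.
#'
#' @inheritParams binomial_sf
#' @return Two-sided p-values.
#' @export
binomial_test_two_sided <- function(k, n, p0) {
  pmin(1, 2 * pmin(binomial_cdf(k, n, p0), binomial_sf(k, n, p0)))
}
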