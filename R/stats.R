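# Shared hypothesis-testing primitives. Every routine here has an
# independent oracle in the test suite (stats::t.test, stats::p.adjust,
# stats::binom.test, enumeration); keep these implementations closed-form.

#' Welch's two-sample t-test
#'
#' Unequal-variance two-sample t statistic with Welch-Satterthwaite degrees
#' of freedom and a two-sided p-value. This is the package-wide two-group
#' location test (all tests in the pipeline are two-sided).
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @return list with elements `t`, `df`, `p`.
#' @export
welch_t <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  assert_that(length(x) >= 2 && length(y) >= 2,
              "welch_t: each group needs n >= 2")
  nx <- length(x); ny <- length(y)
  vx <- var(x); vy <- var(y)
  if (vx == 0 && vy == 0) {
    stop("welch_t: zero variance in both groups (degenerate input)")
  }
  se2 <- vx / nx + vy / ny
  tt <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = tt, df = df, p = 2 * pt(-abs(tt), df))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement; output is bounded
#' by 1 and never smaller than the input p.
#'
#' @param p numeric vector of p-values.
#' @return adjusted p-values in the original order.
#' @export
bh_adjust <- function(p) {
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(m / (m:1) * p[o]))[ro]
  q
}

#' Holm adjusted p-values
#'
#' Step-down family-wise error control. `m` may exceed `length(p)` when the
#' family is larger than the p-values passed in.
#'
#' @param p numeric vector of p-values.
#' @param m family size (default `length(p)`).
#' @return adjusted p-values in the original order.
#' @export
holm_adjust <- function(p, m = length(p)) {
  k <- length(p)
  if (k == 0) return(numeric(0))
  assert_that(m >= k, "holm_adjust: m must be >= length(p)")
  o <- order(p)
  ro <- order(o)
  pmin(1, cummax((m - seq_len(k) + 1) * p[o]))[ro]
}

#' Pearson correlation with a t-based two-sided p-value
#'
#' @param x,y paired numeric vectors, n >= 3.
#' @return list with `r`, `n`, `t`, `p`.
#' @export
pearson_cor <- function(x, y) {
  assert_that(length(x) == length(y), "pearson_cor: unequal lengths")
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  assert_that(n >= 3, "pearson_cor: need n >= 3 pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    stop("pearson_cor: zero variance in one of the variables")
  }
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  if (abs(r) >= 1) {
    return(list(r = sign(r), n = n, t = sign(r) * Inf, p = 0))
  }
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, n = n, t = tt, p = 2 * pt(-abs(tt), n - 2))
}

#' Exact two-sided binomial test (minimum-likelihood definition)
#'
#' Two-sided p-value summing the probabilities of all outcomes no more
#' likely than the observed count, the convention used by
#' `stats::binom.test`.
#'
#' @param k observed successes.
#' @param n trials.
#' @param p0 null success probability, strictly inside (0, 1).
#' @return p-value in `[0, 1]`.
#' @export
binom_test_minlik <- function(k, n, p0) {
  assert_that(p0 > 0 && p0 < 1, "binom_test_minlik: p0 must be in (0,1)")
  assert_that(k >= 0 && k <= n, "binom_test_minlik: k out of range")
  d <- dbinom(0:n, n, p0)
  # 1 + 1e-7 relative slack guards against floating-point ties
  min(1, sum(d[d <= d[k + 1] * (1 + 1e-7)]))
}
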