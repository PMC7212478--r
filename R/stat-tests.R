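#' Vectorized two-sided Fisher exact test for 2x2 tables
#'
#' Computes the same two-sided p-value as `stats::fisher.test` on the table
#' `rbind(c(a, b), c(c, d))` (sum of hypergeometric point probabilities not
#' exceeding that of the observed table, with the usual 1e-7 relative
#' tolerance), vectorized over tables and de-duplicated so that repeated
#' count configurations are evaluated once. Used for per-CpG differential
#' methylation where millions of small tables arise.
#'
#' @param a,b,c,d integer vectors: cells of the 2x2 tables, recycled to a
#'   common length.
#' @return numeric vector of two-sided p-values.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.integer(a), n); b <- rep_len(as.integer(b), n)
  c <- rep_len(as.integer(c), n); d <- rep_len(as.integer(d), n)
  if (any(a < 0 | b < 0 | c < 0 | d < 0)) stop("negative cell counts")
  key <- paste(a, b, c, d, sep = ",")
  first <- !duplicated(key)
  p1 <- mapply(function(a, b, c, d) {
    r1 <- a + b; r2 <- c + d; k <- a + c
    lo <- max(0L, k - r2); hi <- min(k, r1)
    dens <- stats::dhyper(lo:hi, r1, r2, k)
    sum(dens[dens <= dens[a - lo + 1L] * (1 + 1e-7)])
  }, a[first], b[first], c[first], d[first])
  pmin(unname(p1[match(key, key[first])]), 1)
}

#' One-sided two-sample Kolmogorov-Smirnov test
#'
#' Directional comparison of two empirical distributions. With
#' `alternative = "greater"` the alternative is that `x` is stochastically
#' larger than `y` (its CDF lies below), the direction expected for genes in
#' copy-number-gain regions versus neutral genes; `"less"` is the mirror for
#' loss regions.
#'
#' @param x,y numeric samples.
#' @param alternative `"greater"` (x shifted up) or `"less"` (x shifted down).
#' @return list with `D` (one-sided statistic) and `p`.
#' @export
ks_one_sided <- function(x, y, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  ## stats::ks.test's "greater"/"less" speak about the CDF of x, which is the
  ## opposite of stochastic ordering; map our shift language onto it.
  alt_cdf <- if (alternative == "greater") "less" else "greater"
  kt <- suppressWarnings(stats::ks.test(x, y, alternative = alt_cdf))
  list(D = unname(kt$statistic), p = unname(kt$p.value))
}

#' Exact binomial overlap test between two gene sets
#'
#' Tests whether the observed overlap `k` between a gene set of size `n` and
#' a second set covering fraction `p0` of the universe is compatible with
#' independent draws. Both tail probabilities are reported because either an
#' excess or a deficit of overlap can be of interest.
#'
#' @param k observed overlap size.
#' @param n size of the first set.
#' @param p0 background success probability (fraction of the universe in the
#'   second set).
#' @return list with `p_two_sided`, `p_enrichment` (P(X >= k)), and
#'   `p_depletion` (P(X <= k)).
#' @export
binomial_overlap_test <- function(k, n, p0) {
  stopifnot(k >= 0, n >= k, p0 >= 0, p0 <= 1)
  list(
    p_two_sided  = stats::binom.test(k, n, p0)$p.value,
    p_enrichment = stats::pbinom(k - 1, n, p0, lower.tail = FALSE),
    p_depletion  = stats::pbinom(k, n, p0)
  )
}

#' Benjamini-Hochberg adjustment (thin wrapper, kept for a single call site)
#' @noRd
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")
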