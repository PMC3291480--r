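#' Wilcoxon matched-pairs signed-rank test
#'
#' Two-tailed matched-pairs signed-rank test with the min-signed-rank-sum
#' convention: zero differences are dropped, absolute differences are
#' ranked with mid-ranks for ties, and the reported statistic is
#' `V = min(W+, W-)`, so a set of pairs that all differ in the same
#' direction gives `V = 0`. The p-value is exact (computed from the full
#' permutation distribution of signs, handling mid-ranks) for up to 15
#' informative pairs, and a tie-corrected normal approximation beyond
#' that.
#'
#' @param x,y Numeric vectors of equal length (paired observations).
#' @return A list with `V`, `p`, and `n_used` (informative pairs). If all
#'   differences are zero the test is undefined and `V`/`p` are `NA`.
#' @export
#' @examples
#' wilcoxon_matched_pairs(c(5, 6, 7, 8, 9, 10, 11), c(1, 2, 3, 4, 5, 6, 7))
wilcoxon_matched_pairs <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(list(V = NA_real_, p = NA_real_, n_used = 0L))
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r[d < 0])
  V <- min(w_plus, w_minus)
  if (n <= 15L) {
    # exact distribution of W+ by convolution over doubled ranks
    # (mid-ranks are multiples of 1/2, so doubling gives integers)
    r2 <- as.integer(round(2 * r))
    dist <- c(1, numeric(sum(r2)))
    for (ri in r2) {
      shifted <- c(numeric(ri), dist[seq_len(length(dist) - ri)])
      dist <- dist + shifted
    }
    dist <- dist / 2^n
    w2 <- as.integer(round(2 * w_plus))
    p_le <- sum(dist[seq_len(w2 + 1L)])
    p_ge <- sum(dist[(w2 + 1L):length(dist)])
    p <- min(1, 2 * min(p_le, p_ge))
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w_plus - mu) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(V = V, p = p, n_used = n)
}

#' Friedman rank test for repeated measures
#'
#' Friedman's analysis of variance by ranks for a birds-by-conditions
#' matrix: observations are ranked within each row (mid-ranks for ties)
#' and the tie-corrected chi-square statistic with `k - 1` degrees of
#' freedom is returned. With `n` rows and `k` all-distinct columns in a
#' common order the statistic attains its maximum `n * (k - 1)`.
#'
#' @param mat Numeric matrix, one row per subject, one column per
#'   condition (`k >= 2`).
#' @return A list with `chi2`, `df` and `p`.
#' @export
friedman_rank_test <- function(mat) {
  mat <- as.matrix(mat)
  n <- nrow(mat)
  k <- ncol(mat)
  stopifnot(k >= 2L, n >= 1L)
  rk <- t(apply(mat, 1L, rank))
  Rj <- colSums(rk)
  tie_term <- sum(apply(mat, 1L, function(row) {
    u <- table(row)
    sum(u^3 - u)
  }))
  denom <- n * k * (k + 1) - tie_term / (k - 1)
  # fully tied rows degenerate to 0/0: no evidence of any difference
  chi2 <- if (denom <= 0) 0 else 12 * sum((Rj - n * (k + 1) / 2)^2) / denom
  df <- k - 1
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE))
}
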