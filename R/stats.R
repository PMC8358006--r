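## Self-contained statistical kernels. These are deliberately written out
## rather than delegated so that the exact-enumeration and approximation
## branches can be tested against independent oracles.

test_result <- function(statistic, p_value, method, n1, n2) {
  stopifnot(p_value >= 0, p_value <= 1 + 1e-12)
  list(statistic = statistic, p_value = min(p_value, 1),
       method = method, n1 = n1, n2 = n2)
}

mw_u <- function(x, y) {
  # U statistic of x: #{(i,j): x_i > y_j} + 0.5 #{ties}
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Exact enumeration over all label arrangements when `n1 + n2 <= 16`
#' (handles ties exactly); otherwise normal approximation with midrank tie
#' correction and a 0.5 continuity correction. The two-sided exact p counts
#' arrangements with `|U - n1*n2/2|` at least as large as observed (the
#' permutation distribution of U is symmetric about its mean).
#'
#' @param x,y numeric samples (each non-empty).
#' @param alternative `"two-sided"` (default), `"greater"` or `"less"`;
#'   "greater" means x stochastically larger than y.
#' @return list with `statistic` (U of x), `p_value`, `method`, `n1`, `n2`.
#' @export
mann_whitney <- function(x, y, alternative = c("two-sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(x) < 1 || length(y) < 1) stop("empty sample in mann_whitney")
  if (anyNA(x) || anyNA(y)) stop("NA in mann_whitney input")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  u <- mw_u(x, y)
  mu <- n1 * n2 / 2
  if (N <= 16) {
    pool <- c(x, y)
    r <- rank(pool)
    cmb <- utils::combn(N, n1)
    us <- colSums(matrix(r[cmb], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- switch(alternative,
                "two-sided" = mean(abs(us - mu) >= abs(u - mu) - 1e-9),
                "greater" = mean(us >= u - 1e-9),
                "less" = mean(us <= u + 1e-9))
    return(test_result(u, p, "mann_whitney_exact", n1, n2))
  }
  # normal approximation with tie correction
  ties <- table(c(x, y))
  sig2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  sig <- sqrt(max(sig2, .Machine$double.eps))
  z_g <- (u - mu - 0.5) / sig
  z_l <- (u - mu + 0.5) / sig
  p <- switch(alternative,
              "two-sided" = min(1, 2 * min(stats::pnorm(z_g, lower.tail = FALSE),
                                           stats::pnorm(z_l))),
              "greater" = stats::pnorm(z_g, lower.tail = FALSE),
              "less" = stats::pnorm(z_l))
  test_result(u, p, "mann_whitney_normal", n1, n2)
}

#' Rank (Spearman) and Pearson correlation with t-approximation p-value
#'
#' Spearman is computed as Pearson on midranks. p-value from the
#' t distribution with n-2 degrees of freedom (two-sided).
#'
#' @param x,y equal-length numeric vectors, length >= 3.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return list with `r` in `[-1, 1]` and `p`.
#' @export
rank_correlation <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop("NA in rank_correlation input")
  if (stats::sd(x) == 0) stop("constant vector: x")
  if (stats::sd(y) == 0) stop("constant vector: y")
  if (method == "spearman") { x <- rank(x); y <- rank(y) }
  r <- stats::cor(x, y)
  n <- length(x)
  if (abs(r) >= 1 - 1e-12) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(r = r, p = p, method = method, n = n)
}

#' Upper-tail hypergeometric enrichment
#'
#' P(X >= k) for k hits in a set of size n, where the term has K members in
#' a universe of N genes; enrichment factor is observed/expected hit rate,
#' `(k/n)/(K/N)`.
#'
#' @param k,n,K,N integers; `0 <= k <= min(n, K)`, `n, K <= N`.
#' @param ef_cut,p_cut reporting thresholds for the `enriched` flag
#'   (defaults: enrichment factor > 1.5 and p < 0.01).
#' @return list: `k, n, K, N, p_hyper, enrichment_factor, enriched`.
#' @export
hypergeometric_enrichment <- function(k, n, K, N, ef_cut = 1.5, p_cut = 0.01) {
  if (k < 0 || n < 0 || K < 0 || N < 1 || k > min(n, K) || n > N || K > N)
    stop("inconsistent hypergeometric counts (k=", k, ", n=", n,
         ", K=", K, ", N=", N, ")")
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  ef <- if (n > 0 && K > 0) (k / n) / (K / N) else NA_real_
  list(k = k, n = n, K = K, N = N, p_hyper = p, enrichment_factor = ef,
       enriched = !is.na(ef) && ef > ef_cut && p < p_cut)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up procedure: adjusted p for the i-th smallest p is
#' `min_{j >= i} p_(j) * m / j`, capped at 1; order-preserving.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return adjusted p-values in the input order.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must be in [0, 1]")
  m <- length(pvalues)
  o <- order(pvalues, decreasing = TRUE)
  adj <- pmin(1, cummin(pvalues[o] * m / seq(m, 1)))
  adj[order(o)]
}

#' Empirical p-value with add-one correction
#'
#' `p = (1 + #draws as-or-more-extreme) / (1 + n_draws)`; never zero.
#'
#' @param observed observed statistic.
#' @param null_draws numeric vector of null statistics (non-empty).
#' @param tail `"greater"` or `"less"`.
#' @export
empirical_p <- function(observed, null_draws, tail = c("greater", "less")) {
  tail <- match.arg(tail)
  if (length(null_draws) < 1) stop("empty null sample")
  extreme <- if (tail == "greater") sum(null_draws >= observed)
             else sum(null_draws <= observed)
  (1 + extreme) / (1 + length(null_draws))
}
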