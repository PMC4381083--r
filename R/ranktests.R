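#' Two-sided Mann-Whitney rank-sum test
#'
#' Compares two samples by the Mann-Whitney U statistic computed from
#' average ranks (ties allowed).  When `min(n, m) <= exact_max` the
#' p-value is exact: all `choose(n+m, n)` assignments of the pooled
#' values to the two groups are enumerated and the two-sided p-value is
#' `min(1, 2 * min(P(U <= u), P(U >= u)))`.  For larger samples a
#' normal approximation with tie correction and continuity correction
#' is used.
#'
#' @param x,y numeric samples.
#' @param exact_max largest `min(n, m)` for which full enumeration is
#'   performed (enumeration is also skipped when `choose(n+m, n)`
#'   exceeds 2e5, to bound memory and time).
#' @return A list of class `rank_test` with elements `statistic` (U of
#'   the first sample), `p_value`, `method` (`"exact"` or `"normal"`),
#'   `n`, `m`.
#' @export
mann_whitney_test <- function(x, y, exact_max = 8L) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x); m <- length(y)
  if (n == 0L || m == 0L) stop("both samples must be non-empty")
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  if (min(n, m) <= exact_max && choose(n + m, min(n, m)) <= 2e5) {
    us <- u_null_distribution(pooled, n)
    p <- min(1, 2 * min(mean(us <= u + 1e-9), mean(us >= u - 1e-9)))
    method <- "exact"
  } else {
    mu <- n * m / 2
    N <- n + m
    ties <- table(pooled)
    sigma2 <- (n * m / 12) * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- u - mu
      z <- (z - sign(z) * 0.5) / sqrt(sigma2)  # continuity correction
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal"
  }
  structure(list(statistic = u, p_value = p, method = method, n = n, m = m),
            class = "rank_test")
}

# U statistics over all assignments of `n` of the pooled values to
# group 1 (ranks fixed by the pooled sample, so ties are handled by
# average ranks throughout).
u_null_distribution <- function(pooled, n) {
  r <- rank(pooled)
  combs <- utils::combn(length(pooled), n)
  colSums(matrix(r[combs], nrow = n)) - n * (n + 1) / 2
}

#' Two-sided one-sample Wilcoxon signed-rank test
#'
#' Tests whether the sample `x` is symmetric about `mu`.  Differences
#' equal to `mu` are dropped (standard signed-rank convention); ties
#' among the absolute differences get average ranks.  For `n <=
#' exact_max` non-zero differences the null distribution of the
#' positive-rank sum V is enumerated over all `2^n` sign assignments of
#' the observed absolute ranks; otherwise a normal approximation with
#' tie correction and continuity correction is used.  If every value
#' equals `mu` the test is degenerate and an error of class
#' `"degenerate_test"` is signalled.
#'
#' @param x numeric sample.
#' @param mu hypothesized center of symmetry.
#' @param exact_max largest number of non-zero differences for full
#'   enumeration.
#' @return A list of class `rank_test` with `statistic` (V), `p_value`,
#'   `method`, `n` (non-zero differences).
#' @export
signed_rank_test <- function(x, mu = 0, exact_max = 12L) {
  d <- as.numeric(x) - mu
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    stop(structure(class = c("degenerate_test", "error", "condition"),
                   list(message = "all values equal mu: signed-rank test is degenerate",
                        call = sys.call())))
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= exact_max) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    vs <- as.vector(signs %*% r)
    p <- min(1, 2 * min(mean(vs <= v + 1e-9), mean(vs >= v - 1e-9)))
    method <- "exact"
  } else {
    mu_v <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- v - mu_v
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  structure(list(statistic = v, p_value = p, method = method, n = n),
            class = "rank_test")
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf("rank test (%s): statistic = %g, p = %.3g\n",
              x$method, x$statistic, x$p_value))
  invisible(x)
}
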