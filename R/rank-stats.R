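# Rank statistics used across the pipeline: Wilcoxon rank-sum and
# signed-rank tests with exact small-sample enumeration, and
# Benjamini-Hochberg adjustment. Exact paths enumerate the null
# distribution directly so they are verifiable against combinatorial
# oracles; larger samples use the normal approximation with tie and
# continuity corrections.

.test_result <- function(statistic, p, n, method) {
  structure(list(statistic = statistic, p_value = p, n = n, method = method),
            class = "rank_test")
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf("Wilcoxon test (%s): statistic = %g, p = %g, n = %s\n",
              x$method, x$statistic, x$p_value,
              paste(x$n, collapse = "/")))
  invisible(x)
}

# two-sided p from a discrete null distribution of a statistic w:
# doubled smaller tail, capped at 1
.two_sided_tail <- function(null_values, observed) {
  lo <- mean(null_values <= observed + 1e-9)
  hi <- mean(null_values >= observed - 1e-9)
  min(1, 2 * min(lo, hi))
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided test on two independent samples. When the combined size is
#' at most `exact_max` and there are no ties across groups, the p-value
#' is computed by exact enumeration of all rank subsets; otherwise the
#' normal approximation with tie correction and continuity correction is
#' used. Identical groups (zero-variance null) give p = 1.
#'
#' @param x,y numeric vectors (both nonempty).
#' @param exact_max maximum combined sample size for the exact path
#'   (default 12).
#' @return a `rank_test` list: `statistic` (rank sum of `x`), `p_value`,
#'   `n` (per group), `method` (`"exact"` or `"approximate"`).
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 12L) {
  if (length(x) == 0L || length(y) == 0L) stop("both groups must be nonempty")
  nx <- length(x)
  ny <- length(y)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(nx)])
  has_ties <- anyDuplicated(c(x, y)) > 0L
  if (nx + ny <= exact_max && !has_ties) {
    # enumerate every C(nx+ny, nx) assignment of ranks to group x
    subsets <- combn(nx + ny, nx)
    null_w <- colSums(matrix(seq_len(nx + ny)[subsets], nrow = nx))
    p <- .two_sided_tail(null_w, w)
    return(.test_result(w, p, c(nx, ny), "exact"))
  }
  n <- nx + ny
  mu <- nx * (n + 1) / 2
  tie_sizes <- table(c(x, y))
  sigma2 <- nx * ny / 12 *
    ((n + 1) - sum(tie_sizes^3 - tie_sizes) / (n * (n - 1)))
  if (sigma2 <= 0) return(.test_result(w, 1, c(nx, ny), "approximate"))
  z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * pnorm(-abs(z)))
  .test_result(w, p, c(nx, ny), "approximate")
}

#' Wilcoxon signed-rank test
#'
#' Two-sided one-sample (paired-difference) test. Zero differences are
#' dropped (their count is reported). With at most `exact_max` nonzero
#' differences the null distribution of the positive-rank sum is
#' enumerated over all 2^n sign assignments (midranks used for tied
#' magnitudes); otherwise the normal approximation with tie and
#' continuity corrections is used.
#'
#' @param d numeric vector of paired differences.
#' @param exact_max maximum number of nonzero differences for the exact
#'   path (default 12).
#' @return a `rank_test` list: `statistic` (positive-rank sum),
#'   `p_value`, `n` (nonzero differences), `method`; plus `n_zero`.
#' @export
wilcoxon_signed_rank <- function(d, exact_max = 12L) {
  stopifnot(is.numeric(d))
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  if (length(d) == 0L) stop("all differences are zero")
  n <- length(d)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exact_max) {
    # all 2^n sign assignments of the (mid)ranks
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    null_w <- as.numeric(signs %*% r)
    p <- .two_sided_tail(null_w, w)
    res <- .test_result(w, p, n, "exact")
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    if (sigma2 <= 0) {
      res <- .test_result(w, 1, n, "approximate")
    } else {
      z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
      res <- .test_result(w, min(1, 2 * pnorm(-abs(z))), n, "approximate")
    }
  }
  res$n_zero <- n_zero
  res
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' the output order matches the input order and adjusted values are never
#' smaller than the raw ones.
#'
#' @param p numeric vector of p-values, all in (0, 1].
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  stopifnot(is.numeric(p))
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    stop("all p-values must lie in (0, 1]")
  }
  p.adjust(p, method = "BH")
}
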