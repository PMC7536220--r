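#' Fisher exact test on a 2x2 contingency table
#'
#' Exact conditional test of independence for a 2x2 table of counts
#' \preformatted{        col1  col2
#'   row1    a     b
#'   row2    c     d}
#' The one-sided ("greater") p-value is the upper hypergeometric tail of cell
#' `a` given fixed margins; the two-sided p-value sums the probabilities of
#' all margin-fixed tables whose point probability does not exceed the
#' observed one, with a relative tie tolerance of 1e-7. This is the
#' convention used throughout the cohort analyses in this package (e.g. the
#' xenograft engraftment comparison of metastatic vs non-metastatic patient
#' samples, 2/4 vs 0/42, which yields p = 6/1035, printed as 0.006).
#'
#' All combinatorics are computed in log-gamma space, so tables with margins
#' of order 1e5 (whole-transcriptome universes) are handled without overflow.
#'
#' @param a,b,c,d Non-negative integer counts of the 2x2 table.
#' @param alternative `"two.sided"` or `"greater"` (enrichment of cell `a`).
#' @return A one-row tibble with columns `estimate` (sample odds ratio
#'   `ad/bc`; `Inf` when only `bc` is zero, `NaN` when both products are
#'   zero), `p.value`, `alternative` and `method`.
#' @examples
#' fisher_exact_2x2(2, 2, 0, 42)            # p = 6/1035 ~ 0.006
#' fisher_exact_2x2(9, 1, 1, 9, "greater")
#' @export
fisher_exact_2x2 <- function(a, b, c, d,
                             alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("all four counts must be non-negative integers", call. = FALSE)
  }
  n <- sum(counts)
  ad <- a * d
  bc <- b * c
  estimate <- if (bc == 0) {
    if (ad == 0) NaN else Inf
  } else ad / bc
  if (n == 0) {
    p <- 1
  } else {
    m <- a + b              # row-1 margin
    k <- a + c              # col-1 margin
    lo <- max(0L, k - (c + d))
    hi <- min(m, k)
    support <- lo:hi
    logp <- lchoose(m, support) + lchoose(n - m, k - support) - lchoose(n, k)
    if (alternative == "greater") {
      p <- exp(.logsumexp(logp[support >= a]))
    } else {
      obs <- logp[support == a]
      keep <- logp <= obs + log1p(1e-7)
      p <- exp(.logsumexp(logp[keep]))
    }
    p <- min(1, p)
  }
  tibble::tibble(
    estimate = estimate,
    p.value = p,
    alternative = alternative,
    method = "Fisher exact test (2x2)"
  )
}

#' Upper tail of the hypergeometric distribution
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the probability of drawing at
#' least `k` successes in `n` draws without replacement from a universe of
#' `N` objects of which `K` are successes. Computed by direct summation of
#' log-space point probabilities, which keeps the tail exact for universes of
#' ~1e5 genes. This is the test used for differential-gene-list overlaps.
#'
#' @param N Universe size.
#' @param K Number of successes in the universe.
#' @param n Number of draws.
#' @param k Observed number of successes among the draws.
#' @return A one-row tibble with `statistic` (= `k`), `p.value`, `alternative`
#'   and `method`.
#' @examples
#' hypergeometric_tail(10, 5, 5, 5)  # 1/252
#' @export
hypergeometric_tail <- function(N, K, n, k) {
  args <- c(N = N, K = K, n = n, k = k)
  if (any(!is.finite(args)) || any(args < 0) || any(args != round(args)) ||
      K > N || n > N || k > min(n, K)) {
    stop("inconsistent hypergeometric arguments: need 0 <= k <= min(n, K) and K, n <= N",
         call. = FALSE)
  }
  tibble::tibble(
    statistic = k,
    p.value = .hyper_tail(k, N, K, n),
    alternative = "one_sided_greater",
    method = "hypergeometric upper tail"
  )
}

# vectorised upper-tail workhorse (all arguments recycled to common length)
.hyper_tail <- function(k, N, K, n) {
  len <- max(length(k), length(N), length(K), length(n))
  k <- rep_len(k, len); N <- rep_len(N, len)
  K <- rep_len(K, len); n <- rep_len(n, len)
  vapply(seq_len(len), function(i) {
    hi <- min(n[i], K[i])
    if (k[i] > hi) return(0)
    lo <- max(k[i], 0L, n[i] - (N[i] - K[i]))
    x <- lo:hi
    logp <- lchoose(K[i], x) + lchoose(N[i] - K[i], n[i] - x) -
      lchoose(N[i], n[i])
    min(1, exp(.logsumexp(logp)))
  }, numeric(1))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (q-values) controlling the false discovery rate,
#' returned in the input order. Thin, validated wrapper around
#' [stats::p.adjust()] with `method = "BH"`.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @return Numeric vector of BH-adjusted q-values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(p) {
  .assert_prob(p)
  stats::p.adjust(p, method = "BH")
}

#' Non-centered correlation of two fold-change vectors
#'
#' The inner-product correlation `sum(x*y) / sqrt(sum(x^2) * sum(y^2))`,
#' computed without subtracting the vector means, so that agreement is
#' measured relative to zero log fold change rather than to the average fold
#' change of each contrast.
#'
#' @param x,y Numeric vectors of equal length (>= 2), typically per-gene log2
#'   fold changes of two contrasts over a common gene set.
#' @return The non-centered correlation in `[-1, 1]`; `NaN` (with a warning)
#'   when either vector has zero norm.
#' @examples
#' noncentered_cor(c(1, 2), c(2, 4))   # 1
#' noncentered_cor(c(1, 0), c(0, 1))   # 0
#' @export
noncentered_cor <- function(x, y) {
  if (length(x) != length(y)) {
    stop("`x` and `y` must have equal length", call. = FALSE)
  }
  if (length(x) < 2L) stop("need at least 2 paired values", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("fold-change vectors must be finite", call. = FALSE)
  }
  nx <- sum(x^2)
  ny <- sum(y^2)
  if (nx == 0 || ny == 0) {
    warning("zero-norm vector: non-centered correlation is undefined")
    return(NaN)
  }
  r <- sum(x * y) / sqrt(nx * ny)
  max(-1, min(1, r))
}

#' p-value for a (non-centered) correlation via the Student-t law
#'
#' Two-sided p-value obtained by mapping the correlation through
#' `t = r * sqrt((n - 2) / (1 - r^2))` and referring to a Student-t
#' distribution with `n - 2` degrees of freedom, i.e. the exact law of the
#' centered Pearson correlation under independence, applied here to the
#' non-centered statistic as well (see the vignette for the caveat this
#' carries).
#'
#' @param r Correlation in `[-1, 1]`.
#' @param n Number of paired observations (>= 3).
#' @return A one-row tibble with `statistic` (the t value), `df`, `p.value`,
#'   `alternative` and `method`. `|r| = 1` gives `p = 0`.
#' @examples
#' cor_pvalue(0.5, 11)
#' @export
cor_pvalue <- function(r, n) {
  if (!is.finite(n) || n < 3) stop("`n` must be >= 3", call. = FALSE)
  if (!is.finite(r) || abs(r) > 1 + 1e-12) {
    stop("`r` must lie in [-1, 1]", call. = FALSE)
  }
  r <- max(-1, min(1, r))
  if (abs(r) == 1) {
    t <- sign(r) * Inf
    p <- 0
  } else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(t), df = n - 2)
  }
  tibble::tibble(
    statistic = t,
    df = n - 2,
    p.value = p,
    alternative = "two_sided",
    method = "t-distribution correlation test"
  )
}

#' Fisher combination of independent p-values
#'
#' Combines `k` p-values as `X = -2 * sum(log(p))`, referred to a chi-square
#' distribution with `2k` degrees of freedom. Used to aggregate per-cell
#' pathway-enrichment p-values into one cohort-level p-value per pathway.
#' Exact zeros are clamped to the smallest positive double (with a warning)
#' rather than propagated as `-Inf`.
#'
#' @param p Numeric vector of p-values in `(0, 1]` (zeros clamped).
#' @return A one-row tibble with `statistic` (X), `df`, `p.value` and
#'   `method`.
#' @examples
#' combine_pvalues_fisher(c(0.05, 0.05))
#' @export
combine_pvalues_fisher <- function(p) {
  if (length(p) < 1L) stop("need at least one p-value", call. = FALSE)
  .assert_prob(p)
  if (any(p == 0)) {
    warning("p-values of 0 clamped to .Machine$double.xmin")
    p[p == 0] <- .Machine$double.xmin
  }
  X <- -2 * sum(log(p))
  k <- length(p)
  tibble::tibble(
    statistic = X,
    df = 2 * k,
    p.value = stats::pchisq(X, df = 2 * k, lower.tail = FALSE),
    method = "Fisher combination"
  )
}

# scalar p for internal use
.combine_fisher_p <- function(p) {
  p[p == 0] <- .Machine$double.xmin
  stats::pchisq(-2 * sum(log(p)), df = 2 * length(p), lower.tail = FALSE)
}
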