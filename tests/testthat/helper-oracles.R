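# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's code paths (and where possible its numerics):
# factorial arithmetic instead of log-gamma, explicit loops instead of
# vectorised joins.

`%||%` <- function(a, b) if (is.null(a)) b else a

# two-sided Fisher p by enumeration of all margin-fixed tables with exact
# factorial probabilities (totals <= 30 keep factorials exact in doubles)
oracle_fisher_two_sided <- function(a, b, c, d) {
  n <- a + b + c + d
  if (n == 0) return(1)
  m <- a + b
  k <- a + c
  support <- max(0, k - (c + d)):min(m, k)
  prob <- vapply(support, function(x) {
    choose(m, x) * choose(n - m, k - x) / choose(n, k)
  }, numeric(1))
  obs <- prob[support == a]
  sum(prob[prob <= obs * (1 + 1e-7)])
}

# naive O(m^2) BH step-up: q_(i) = min over j >= i of m * p_(j) / j
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- Inf
    for (j in i:m) cand <- min(cand, m * p[ord[j]] / j)
    q[ord[i]] <- min(1, cand)
  }
  q
}

# hypergeometric upper tail by plain summation with choose()
oracle_hyper_tail <- function(N, K, n, k) {
  hi <- min(n, K)
  if (k > hi) return(0)
  xs <- max(k, 0, n - (N - K)):hi
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# per-(cell, bin, type) frequency profile by explicit double loop
oracle_frequency <- function(calls, roster, bins) {
  out <- NULL
  for (g in sort(unique(roster$group))) {
    cells <- roster$cell[roster$group == g]
    for (b in seq_len(nrow(bins))) {
      for (tp in c("gain", "loss")) {
        hit <- 0L
        for (ce in cells) {
          cc <- calls[calls$cell_id == ce & calls$type == tp &
                        calls$chrom == bins$chrom[b], , drop = FALSE]
          any_ov <- FALSE
          if (nrow(cc) > 0) {
            for (i in seq_len(nrow(cc))) {
              if (cc$start[i] <= bins$end[b] && cc$end[i] >= bins$start[b]) {
                any_ov <- TRUE
              }
            }
          }
          hit <- hit + any_ov
        }
        out <- rbind(out, data.frame(
          group = g, chrom = bins$chrom[b], start = bins$start[b],
          type = tp, pct = 100 * hit / length(cells)
        ))
      }
    }
  }
  out
}
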