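# internal helpers shared across modules

# log(sum(exp(x))) without overflow; x may be length 0 -> -Inf
.logsumexp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# deterministic sub-stream seed derived from a global seed and a generator
# name, so independent generators never share a random stream
.substream <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 131 + k) %% 1000003
  as.integer((as.numeric(seed) %% 2147480000 + h) %% 2147483647)
}

.assert_prob <- function(p, what = "p") {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop(sprintf("`%s` must lie in [0, 1]", what), call. = FALSE)
  }
  invisible(p)
}

# Newton inversion of the trigamma function (monotone decreasing on (0, Inf))
.trigamma_inverse <- function(x) {
  stopifnot(is.finite(x), x > 0)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in seq_len(50)) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (abs(dif) < 1e-10 * y) break
  }
  y
}
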