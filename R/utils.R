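# Deterministic hierarchical sub-seed derivation: master seed -> unit
# index (family, site, replicate).  Keeps all derived seeds in the
# 32-bit signed range that set.seed() accepts.
.derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 1000003) %% 2147483587) + 1L
}

.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Equal-tailed quantiles of a weighted discrete distribution.
.weighted_quantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]; w <- w[o] / sum(w)
  cw <- cumsum(w)
  vapply(probs, function(p) {
    i <- which(cw >= p)[1L]
    if (is.na(i)) x[length(x)] else x[i]
  }, numeric(1))
}

# Effective sample size from the autocorrelation function, truncated at
# the first non-positive sum of adjacent autocorrelation pairs
# (initial positive sequence estimator).
.ess <- function(x) {
  n <- length(x)
  if (n < 10L || stats::var(x) == 0) return(n)
  lag_max <- min(n - 1L, 10L * floor(sqrt(n)))
  rho <- stats::acf(x, lag.max = lag_max, plot = FALSE)$acf[-1L]
  npair <- floor(length(rho) / 2)
  s <- 0
  for (k in seq_len(npair)) {
    pair <- rho[2 * k - 1L] + rho[2 * k]
    if (pair <= 0) break
    s <- s + pair
  }
  max(1, n / (1 + 2 * s))
}
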