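# Brute-force reference implementations, kept deliberately naive and
# independent of the package's vectorized code paths.

# MHL by explicit enumeration of every within-read window
mhl_brute <- function(patterns, counts = rep(1L, length(patterns))) {
  L <- max(nchar(patterns))
  tot <- numeric(L)
  meth <- numeric(L)
  for (i in seq_along(patterns)) {
    p <- patterns[i]
    m <- nchar(p)
    for (l in seq_len(m)) {
      for (s in seq_len(m - l + 1L)) {
        w <- substr(p, s, s + l - 1L)
        tot[l] <- tot[l] + counts[i]
        if (w == strrep("1", l)) meth[l] <- meth[l] + counts[i]
      }
    }
  }
  ok <- tot > 0
  l <- seq_len(L)[ok]
  sum(l * meth[ok] / tot[ok]) / sum(l)
}

# maximal qualifying runs by exhaustive enumeration of all site intervals
partition_brute <- function(pair_ok, min_cpgs) {
  n <- length(pair_ok) + 1L           # number of sites
  runs <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (j - i + 1L < min_cpgs) next
      inside <- if (j > i) all(pair_ok[i:(j - 1L)]) else TRUE
      left_ext <- i > 1L && pair_ok[i - 1L]
      right_ext <- j < n && pair_ok[j]
      if (inside && !left_ext && !right_ext)
        runs[[length(runs) + 1L]] <- c(i, j)   # 1-based site ranks
    }
  }
  runs
}

# Benjamini-Hochberg step-up by direct definition
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  if (m > 1L) for (i in (m - 1L):1L) q[i] <- min(q[i], q[i + 1L])
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# small fast cohort for unit tests
small_config <- function(...) {
  args <- utils::modifyList(
    list(n_samples = 10, n_blocks = 40, n_signature_blocks = 8, coverage = 15),
    list(...))
  do.call(simulation_config, args)
}
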