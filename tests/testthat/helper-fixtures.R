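# Shared fixture builders. Everything is generated in code; no data files.

noise_trace <- function(duration_s = 20, rate_hz = 5000, sd = 2, seed = 1) {
  set.seed(seed)
  recording(stats::rnorm(duration_s * rate_hz, 0, sd), rate_hz, units = "pA")
}

# A trace with one scripted plateau envelope (raised-cosine edges).
envelope_trace <- function(amp, dur_ms, noise = 2, rate_hz = 5000,
                           duration_s = 20, seed = 1, edge_s = 0.05) {
  set.seed(seed)
  n <- duration_s * rate_hz
  x <- stats::rnorm(n, 0, noise)
  i0 <- round(duration_s / 2 * rate_hz)
  len <- round((dur_ms / 1000 + 2 * edge_s) * rate_hz)
  tt <- (seq_len(len) - 1) / rate_hz
  x[i0:(i0 + len - 1)] <- x[i0:(i0 + len - 1)] +
    amp * ephyr:::plateau_envelope(tt, dur_ms / 1000, edge_s)
  recording(x, rate_hz, units = "pA")
}

# Brute-force recursive flood fill, deliberately written differently from
# the package implementation, as the connected-component oracle.
oracle_max_component <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  grow <- function(r, c) {
    if (r < 1 || r > nr || c < 1 || c > nc) return(0L)
    if (seen[r, c] || !mask[r, c]) return(0L)
    seen[r, c] <<- TRUE
    s <- 1L
    for (dr in -1:1) for (dc in -1:1) {
      if (dr != 0L || dc != 0L) s <- s + grow(r + dr, c + dc)
    }
    s
  }
  best <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (mask[r, c] && !seen[r, c]) best <- max(best, grow(r, c))
  }
  best
}

# Independent Poisson upper-tail by direct summation.
oracle_poisson_tail_log10 <- function(n, t, lambda) {
  mu <- lambda * t
  -log10(sum(stats::dpois(n:(n + 500), mu)))
}
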