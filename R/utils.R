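# Internal signal-processing helpers shared across modules.

# Zero-phase Butterworth filtering of one numeric vector.
# type: "low", "high", "pass" (band-pass takes w = c(lo, hi) in Hz).
butter_filtfilt <- function(x, rate_hz, w_hz, type = c("low", "high", "pass"),
                            order = 4L) {
  type <- match.arg(type)
  nyq <- rate_hz / 2
  W <- w_hz / nyq
  if (any(W <= 0) || any(W >= 1)) {
    stop("filter corner(s) must lie strictly inside (0, Nyquist)")
  }
  bf <- signal::butter(order, W, type = switch(type, low = "low",
                                               high = "high", pass = "pass"))
  # Odd-reflection padding at both ends: filtfilt's own end handling
  # leaves transients proportional to the local offset and slope; odd
  # reflection continues both continuously, so constants and ramps pass
  # without edge artifacts.
  n <- length(x)
  npad <- min(n - 1L, max(100L, round(6 * rate_hz / min(w_hz))))
  if (npad > 0L) {
    head_pad <- 2 * x[1L] - x[(npad + 1L):2L]
    tail_pad <- 2 * x[n] - x[(n - 1L):(n - npad)]
    xp <- c(head_pad, x, tail_pad)
  } else {
    xp <- x
  }
  y <- as.numeric(signal::filtfilt(bf, xp))
  y[(npad + 1L):(npad + n)]
}

# Robust SD: MAD scaled for Gaussian consistency.
robust_sd <- function(x) stats::mad(x, constant = 1.4826)

# Centered moving-average smoothing (odd window, edges padded by reflection).
boxcar_smooth <- function(x, k) {
  k <- as.integer(k)
  if (k <= 1L) return(x)
  if (k %% 2L == 0L) k <- k + 1L
  h <- (k - 1L) %/% 2L
  xp <- c(rev(x[seq_len(h) + 1L]), x, rev(x[length(x) - seq_len(h)]))
  as.numeric(stats::filter(xp, rep(1 / k, k), sides = 2))[(h + 1L):(h + length(x))]
}

# Gaussian smoothing with kernel truncated at 4 sigma (sigma in samples).
gaussian_smooth <- function(x, sigma_samples) {
  if (sigma_samples <= 0) return(x)
  h <- max(1L, ceiling(4 * sigma_samples))
  g <- stats::dnorm(seq(-h, h), sd = sigma_samples)
  g <- g / sum(g)
  xp <- c(rep(x[1L], h), x, rep(x[length(x)], h))
  as.numeric(stats::filter(xp, g, sides = 2))[(h + 1L):(h + length(x))]
}

# Runs of TRUE in a logical vector -> data.frame(start, end) of indices
# (inclusive). Zero-row frame when no run.
true_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

# Merge index runs whose gap (in samples) is < max_gap.
merge_runs <- function(runs, max_gap) {
  if (nrow(runs) <= 1L) return(runs)
  out <- runs[1L, , drop = FALSE]
  for (i in 2L:nrow(runs)) {
    if (runs$start[i] - out$end[nrow(out)] - 1L < max_gap) {
      out$end[nrow(out)] <- runs$end[i]
    } else {
      out <- rbind(out, runs[i, , drop = FALSE])
    }
  }
  out
}

# Local maxima indices of x above a threshold (strict neighbours).
local_maxima_above <- function(x, thr) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  i <- 2L:(n - 1L)
  i[x[i] > thr & x[i] >= x[i - 1L] & x[i] > x[i + 1L]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Linear interpolation through (centers, mu) evaluated at 1..n, with
# linear extrapolation beyond the first/last center (a clamped edge would
# leave residual drift in the first and last half-windows of a windowed
# demeaning scheme).
interp_extrap <- function(centers, mu, n) {
  out <- stats::approx(centers, mu, xout = seq_len(n), rule = 2)$y
  k <- length(centers)
  if (k >= 2L) {
    sl1 <- (mu[2L] - mu[1L]) / (centers[2L] - centers[1L])
    lo <- seq_len(n) < centers[1L]
    out[lo] <- mu[1L] + (which(lo) - centers[1L]) * sl1
    sl2 <- (mu[k] - mu[k - 1L]) / (centers[k] - centers[k - 1L])
    hiw <- which(seq_len(n) > centers[k])
    out[hiw] <- mu[k] + (hiw - centers[k]) * sl2
  }
  out
}
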