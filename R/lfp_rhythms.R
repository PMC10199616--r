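#' Preprocess an LFP recording
#'
#' Zero-phase low-pass at `lp_hz` (default 350 Hz) and per-channel mean
#' subtraction over the full recording.
#'
#' @param rec multichannel [recording()], rate >= 1 kHz.
#' @param lp_hz low-pass corner; clipped to 80% of Nyquist.
#' @return a demeaned, low-passed [recording()].
#' @export
preprocess_lfp <- function(rec, lp_hz = 350) {
  stopifnot(inherits(rec, "recording"))
  rate <- rec$rate_hz
  x <- rec$samples
  cut <- min(lp_hz, 0.8 * rate / 2)
  for (ch in seq_len(nrow(x))) {
    x[ch, ] <- butter_filtfilt(x[ch, ], rate, cut, "low")
  }
  x <- x - rowMeans(x)
  recording(x, rate, channel_ids = rec$channel_ids,
            geometry = rec$geometry, units = rec$units)
}

#' Cut a recording into fixed-length behavioral-state segments
#'
#' Tiles non-overlapping `len_s` segments inside each behavioral epoch;
#' the remainder shorter than `len_s` is discarded, so segments never
#' straddle a state boundary.
#'
#' @param rec a [recording()].
#' @param epochs epoch table (`start_s`, `end_s`, `state`), see
#'   [read_epoch_table()].
#' @param len_s segment length (default 3 s).
#' @return list of segments, each a list with `start_s`, `state`,
#'   `samples` (channels x time matrix) and `rate_hz`.
#' @export
epoch_signal <- function(rec, epochs, len_s = 3) {
  stopifnot(inherits(rec, "recording"))
  epochs <- validate_epochs(epochs)
  rate <- rec$rate_hz
  n <- ncol(rec$samples)
  out <- list()
  for (i in seq_len(nrow(epochs))) {
    k <- floor((epochs$end_s[i] - epochs$start_s[i]) / len_s)
    if (k < 1L) next
    for (j in seq_len(k)) {
      s0 <- epochs$start_s[i] + (j - 1L) * len_s
      i0 <- round(s0 * rate) + 1L
      i1 <- i0 + round(len_s * rate) - 1L
      if (i1 > n) next
      out[[length(out) + 1L]] <- list(
        start_s = s0, state = epochs$state[i],
        samples = rec$samples[, i0:i1, drop = FALSE], rate_hz = rate)
    }
  }
  out
}

# Complex Morlet transform of one signal at the given frequencies, via
# FFT: the wavelet is a Gaussian of width sigma_t = n_cycles/(2*pi*f) in
# time (a Gaussian centered on f in frequency), one-sided (analytic),
# and L2 (energy) normalized, so white noise yields the same expected
# power at every analysis frequency — the property that makes band power
# proportional to band width on a flat spectrum. Returns
# list(coef = complex matrix [freq x time], edge = integer vector of
# per-frequency edge samples without full wavelet support (2 sigma_t)).
morlet_tfr <- function(x, rate_hz, freqs, n_cycles = 7) {
  n <- length(x)
  N <- stats::nextn(2L * n, 2)
  X <- stats::fft(c(x, rep(0, N - n)))
  f_axis <- (0:(N - 1)) / N * rate_hz
  coef <- matrix(0 + 0i, nrow = length(freqs), ncol = n)
  edge <- integer(length(freqs))
  half <- f_axis <= rate_hz / 2
  for (i in seq_along(freqs)) {
    f0 <- freqs[i]
    sigma_t <- n_cycles / (2 * pi * f0)
    H <- numeric(N)
    H[half] <- exp(-2 * pi^2 * sigma_t^2 * (f_axis[half] - f0)^2)
    H <- H / sqrt(sum(H^2) / N)       # unit wavelet energy
    W <- stats::fft(X * H, inverse = TRUE) / N
    coef[i, ] <- 2 * W[seq_len(n)]
    edge[i] <- min(n %/% 2L, ceiling(2 * sigma_t * rate_hz))
  }
  list(coef = coef, edge = edge, freqs = freqs)
}

#' Mean Morlet band power of a segment
#'
#' Complex Morlet convolution on a 1 Hz frequency grid across the band;
#' power `|W|^2` is averaged over time (excluding edge samples without
#' full wavelet support) and summed over the band's frequency grid. With
#' the energy-normalized wavelets this makes the band power of white
#' noise proportional to the band width.
#'
#' @param x numeric vector (one channel of one segment) or a segment from
#'   [epoch_signal()] (first channel used).
#' @param rate_hz sampling rate (taken from a segment when omitted).
#' @param band `c(lo, hi)` in Hz; the canonical bands are theta 3-12,
#'   low theta 3-6, high theta 7-13, gamma 20-90.
#' @param n_cycles wavelet width in cycles (default 7).
#' @return mean band power (squared signal units).
#' @export
morlet_band_power <- function(x, rate_hz = NULL, band, n_cycles = 7) {
  if (is.list(x) && !is.null(x$samples)) {
    rate_hz <- x$rate_hz
    x <- x$samples[1, ]
  }
  if (is.null(rate_hz)) stop("rate_hz required")
  if (band[1] < 1 / (length(x) / rate_hz)) {
    stop("band low edge below the segment's frequency resolution")
  }
  freqs <- seq(band[1], band[2], by = 1)
  tfr <- morlet_tfr(x, rate_hz, freqs, n_cycles)
  pw <- vapply(seq_along(freqs), function(i) {
    e <- tfr$edge[i]
    v <- Mod(tfr$coef[i, ])^2
    mean(v[(e + 1L):(length(v) - e)])
  }, 0)
  sum(pw)
}

#' Band power table for a set of state segments
#'
#' Convenience wrapper computing [morlet_band_power()] for each segment
#' and each named band.
#'
#' @param segments list from [epoch_signal()].
#' @param bands named list of `c(lo, hi)` bands.
#' @param n_cycles wavelet width.
#' @return data frame (`epoch`, `start_s`, `state`, `band`, `power`).
#' @export
band_power_table <- function(segments,
                             bands = list(theta = c(3, 12),
                                          low_theta = c(3, 6),
                                          high_theta = c(7, 13),
                                          gamma = c(20, 90)),
                             n_cycles = 7) {
  rows <- list()
  for (i in seq_along(segments)) {
    for (b in names(bands)) {
      rows[[length(rows) + 1L]] <- data.frame(
        epoch = i, start_s = segments[[i]]$start_s,
        state = segments[[i]]$state, band = b,
        power = morlet_band_power(segments[[i]], band = bands[[b]],
                                  n_cycles = n_cycles))
    }
  }
  do.call(rbind, rows)
}

#' Theta-phase to gamma-power coupling profile
#'
#' For every sample of every segment, the theta phase is the angle of the
#' complex Morlet coefficient at `theta_hz` and the gamma power is the
#' mean `|W|^2` over the gamma band (1 Hz grid). Samples are assigned to
#' 8 equal phase bins partitioning `[-pi, pi)` and the mean gamma power
#' per bin is returned, pooled over segments. Edge samples without full
#' wavelet support at `theta_hz` are excluded.
#'
#' @param segments list from [epoch_signal()] (or a single numeric vector
#'   with `rate_hz` given via attribute-free argument list entries).
#' @param theta_hz phase-providing frequency (default 7).
#' @param gamma_band gamma band (default 20-90 Hz).
#' @param n_bins number of phase bins (default 8).
#' @param n_cycles wavelet width.
#' @return data frame of class `phase_gamma_profile`:
#'   (`bin`, `bin_center_rad`, `mean_gamma_power`, `n_samples`). Empty
#'   bins carry `NA` power and are flagged by attribute `empty_bins`.
#' @export
phase_gamma_profile <- function(segments, theta_hz = 7,
                                gamma_band = c(20, 90), n_bins = 8,
                                n_cycles = 7) {
  if (!length(segments)) stop("need at least one segment")
  gfreqs <- seq(gamma_band[1], gamma_band[2], by = 1)
  phases <- list()
  powers <- list()
  for (seg in segments) {
    x <- seg$samples[1, ]
    rate <- seg$rate_hz
    th <- morlet_tfr(x, rate, theta_hz, n_cycles)
    e <- th$edge[1]
    valid <- (e + 1L):(length(x) - e)
    ph <- Arg(th$coef[1, valid])
    gm <- morlet_tfr(x, rate, gfreqs, n_cycles)
    gp <- colMeans(Mod(gm$coef[, valid, drop = FALSE])^2)
    phases[[length(phases) + 1L]] <- ph
    powers[[length(powers) + 1L]] <- gp
  }
  ph <- unlist(phases)
  gp <- unlist(powers)
  width <- 2 * pi / n_bins
  bin <- pmin(floor((ph + pi) / width) + 1L, n_bins)  # [-pi, pi) partition
  centers <- -pi + (seq_len(n_bins) - 0.5) * width
  mean_p <- rep(NA_real_, n_bins)
  n_s <- integer(n_bins)
  for (b in seq_len(n_bins)) {
    sel <- bin == b
    n_s[b] <- sum(sel)
    if (n_s[b] > 0) mean_p[b] <- mean(gp[sel])
  }
  out <- data.frame(bin = seq_len(n_bins), bin_center_rad = centers,
                    mean_gamma_power = mean_p, n_samples = n_s)
  attr(out, "empty_bins") <- which(n_s == 0L)
  class(out) <- c("phase_gamma_profile", class(out))
  out
}

#' Replicate phase-gamma profiles for a group comparison
#'
#' Splits a set of state segments round-robin into `n_splits` subsets and
#' computes one [phase_gamma_profile()] per subset, stacked into one data
#' frame. Feeding replicate profiles (rather than a single pooled one) to
#' [compare_quadratic_fits()] is what makes its extra-sum-of-squares F
#' test calibrated: the residual then contains genuine between-replicate
#' variation of the profile shape, exactly as replicate animals do in a
#' group comparison.
#'
#' The default wavelet width here is `n_cycles = 3`, narrower than the
#' band-power default of 7: the wavelet's temporal envelope smooths gamma
#' power across neighbouring theta-phase bins, and with 7 cycles at gamma
#' frequencies that smoothing (about a full theta cycle) correlates the
#' bin means of a profile, which inflates the F test's false-positive
#' rate well above nominal. Three cycles keep adjacent bins nearly
#' independent while still isolating the band.
#'
#' @param segments list from [epoch_signal()] (typically one behavioral
#'   state).
#' @param n_splits number of replicate subsets (default 5).
#' @inheritParams phase_gamma_profile
#' @return stacked data frame of `n_splits` profiles with a `replicate`
#'   column.
#' @export
phase_gamma_replicates <- function(segments, n_splits = 5, theta_hz = 7,
                                   gamma_band = c(20, 90), n_bins = 8,
                                   n_cycles = 3) {
  if (length(segments) < n_splits) {
    stop("need at least `n_splits` segments")
  }
  grp <- rep(seq_len(n_splits), length.out = length(segments))
  out <- lapply(seq_len(n_splits), function(g) {
    pr <- phase_gamma_profile(segments[grp == g], theta_hz = theta_hz,
                              gamma_band = gamma_band, n_bins = n_bins,
                              n_cycles = n_cycles)
    pr$replicate <- g
    pr
  })
  do.call(rbind, out)
}

#' Compare quadratic phase-power fits between two groups
#'
#' Extra-sum-of-squares F test for a nested pair of models on pooled
#' phase-bin data: one shared quadratic `power = a*theta^2 + b*theta + c`
#' for both groups versus separate quadratics per group.
#' `F = [(SS_shared - SS_sep) / (df_shared - df_sep)] / (SS_sep / df_sep)`,
#' with p from the F distribution. Inputs may carry replicate rows per
#' bin (e.g. one profile per animal).
#'
#' By default each profile is normalized to unit mean power before
#' fitting. Absolute power differs between recordings for reasons
#' unrelated to phase coupling (electrode impedance, noise floor), and
#' because such a level shift is shared by all bins of one profile it
#' would otherwise enter the F statistic as a spurious group effect;
#' normalization makes the test a comparison of modulation *shape* and
#' keeps it calibrated under the null.
#'
#' @param profile_a,profile_b data frames with columns `bin_center_rad`
#'   and `mean_gamma_power` (as returned by [phase_gamma_profile()]).
#' @param normalize divide each profile by its mean power first
#'   (default `TRUE`).
#' @return data frame of class `quad_fit_comparison` with `F`, `p`,
#'   `ss_shared`, `ss_separate`, `df_shared`, `df_separate`, and the
#'   per-group coefficients `a`, `b`, `c` (suffixes `_a`, `_b`).
#' @export
compare_quadratic_fits <- function(profile_a, profile_b, normalize = TRUE) {
  grab <- function(p) {
    d <- data.frame(theta = p$bin_center_rad, power = p$mean_gamma_power)
    d <- d[stats::complete.cases(d), , drop = FALSE]
    if (normalize && nrow(d)) d$power <- d$power / mean(d$power)
    d
  }
  da <- grab(profile_a)
  db <- grab(profile_b)
  if (length(unique(c(da$theta, db$theta))) < 4L) {
    stop("need at least 4 distinct phase values for a quadratic comparison")
  }
  fit <- function(d) stats::lm(power ~ theta + I(theta^2), data = d)
  fa <- fit(da)
  fb <- fit(db)
  pooled <- rbind(da, db)
  fs <- fit(pooled)
  ss_sep <- sum(stats::residuals(fa)^2) + sum(stats::residuals(fb)^2)
  ss_shared <- sum(stats::residuals(fs)^2)
  df_sep <- nrow(pooled) - 6L
  df_shared <- nrow(pooled) - 3L
  if (df_sep <= 0L) stop("not enough observations for separate fits")
  Fval <- max(0, (ss_shared - ss_sep) / (df_shared - df_sep)) /
    (ss_sep / df_sep)
  p <- stats::pf(Fval, df_shared - df_sep, df_sep, lower.tail = FALSE)
  out <- data.frame(
    F = Fval, p = p, ss_shared = ss_shared, ss_separate = ss_sep,
    df_shared = df_shared, df_separate = df_sep,
    a_a = stats::coef(fa)[["I(theta^2)"]], b_a = stats::coef(fa)[["theta"]],
    c_a = stats::coef(fa)[["(Intercept)"]],
    a_b = stats::coef(fb)[["I(theta^2)"]], b_b = stats::coef(fb)[["theta"]],
    c_b = stats::coef(fb)[["(Intercept)"]])
  class(out) <- c("quad_fit_comparison", class(out))
  out
}

#' Detect ripples by the envelope z-score (Kay) method
#'
#' Each selected channel is band-pass filtered to the ripple band and
#' squared; the squares are summed across channels, Gaussian-smoothed,
#' and square-rooted to a combined envelope, which is z-scored against
#' its idle-epoch mean and SD. Candidate events are idle intervals where
#' `z >= z_thresh`, extended outward to where `z` returns to
#' `boundary_z` (bounded by the containing idle epoch); candidates
#' closer than `min_gap_ms` are merged and events shorter than
#' `min_dur_ms` dropped.
#'
#' The classical boundary convention extends to the envelope mean
#' (`boundary_z = 0`). Because the smoothed envelope is a correlated
#' noise process, its zero-crossings wander, which adds tens of
#' milliseconds of variance to event durations; the default here is a
#' slightly positive boundary (0.25 SD) that marks essentially the same
#' support but with far smaller variance. Set `boundary_z = 0` for the
#' strict mean-return convention.
#'
#' @param rec preprocessed [recording()].
#' @param epochs epoch table; at least one `idle` epoch is required.
#' @param channels channel ids to combine (default: all channels).
#' @param band ripple band (default `c(150, 200)` Hz).
#' Durations can be reported two ways. `duration_method = "boundary"`
#' takes `end_s - start_s` from the boundary extension. The default
#' `"template"` refits each event: the squared, smoothed envelope is
#' modelled as a raised-cosine (Hann) power burst passed through the
#' *actual* detection chain (band-pass filter, squaring, Gaussian
#' smoothing), and the support of the best-fitting template is reported.
#' Because the band filter rings for roughly the reciprocal bandwidth
#' (~20 ms for a 50 Hz band) and the envelope noise is correlated on the
#' same scale, boundary durations carry tens of milliseconds of bias and
#' variance that the forward-model fit largely removes. `start_s`/`end_s`
#' always follow the boundary convention, so with the template method
#' `duration_ms` is the estimated support of the underlying event rather
#' than `end_s - start_s`.
#'
#' @param z_thresh detection threshold in SD units (default 2).
#' @param boundary_z boundary level to which candidates are extended
#'   (default 0.25; 0 reproduces the mean-return convention).
#' @param duration_method `"template"` (forward-model refit, default) or
#'   `"boundary"` (see Details).
#' @param robust_z z-score the envelope with the idle median and MAD
#'   rather than mean and SD (default `FALSE`, the classical convention;
#'   the non-robust scale, inflated by the events themselves, also keeps
#'   noise excursions from crossing the detection threshold).
#' @param smooth_sigma_ms Gaussian smoothing sigma (default 4 ms).
#' @param min_dur_ms minimum event duration (default 15 ms).
#' @param min_gap_ms merge gap between candidates (default 0: no merge).
#' @return data frame (`start_s`, `end_s`, `duration_ms`, `peak_z`),
#'   non-overlapping, confined to idle epochs.
#' @export
detect_ripples_kay <- function(rec, epochs, channels = NULL,
                               band = c(150, 200), z_thresh = 2,
                               boundary_z = 0.25, robust_z = FALSE,
                               duration_method = c("template", "boundary"),
                               smooth_sigma_ms = 4, min_dur_ms = 15,
                               min_gap_ms = 0) {
  duration_method <- match.arg(duration_method)
  stopifnot(inherits(rec, "recording"))
  epochs <- validate_epochs(epochs)
  idle <- epochs[epochs$state == "idle", , drop = FALSE]
  if (nrow(idle) == 0L) stop("no idle epochs")
  rate <- rec$rate_hz
  n <- ncol(rec$samples)
  channels <- channels %||% rec$channel_ids
  ch_i <- match(channels, rec$channel_ids)
  if (anyNA(ch_i)) stop("unknown channel id(s)")

  hi <- min(band[2], 0.9 * rate / 2)
  s <- numeric(n)
  xf1 <- NULL
  for (i in ch_i) {
    xf <- butter_filtfilt(rec$samples[i, ], rate, c(band[1], hi), "pass")
    if (is.null(xf1)) xf1 <- xf
    s <- s + xf^2
  }
  sig_n <- smooth_sigma_ms / 1000 * rate
  s <- gaussian_smooth(s, sig_n)
  env <- sqrt(pmax(s, 0))

  idx_of <- function(t) pmin(pmax(floor(t * rate) + 1L, 1L), n)
  idle_mask <- rep(FALSE, n)
  for (i in seq_len(nrow(idle))) {
    idle_mask[idx_of(idle$start_s[i]):idx_of(idle$end_s[i] - 1 / rate)] <- TRUE
  }
  if (robust_z) {
    mu <- stats::median(env[idle_mask])
    sdv <- stats::mad(env[idle_mask])
  } else {
    mu <- mean(env[idle_mask])
    sdv <- stats::sd(env[idle_mask])
  }
  if (sdv == 0) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      duration_ms = numeric(0), peak_z = numeric(0)))
  }
  z <- (env - mu) / sdv

  runs <- true_runs(z >= z_thresh & idle_mask)
  if (nrow(runs) == 0L) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      duration_ms = numeric(0), peak_z = numeric(0)))
  }
  # extend to z <= boundary_z within the containing idle epoch
  epoch_bounds <- function(i) {
    for (k in seq_len(nrow(idle))) {
      a <- idx_of(idle$start_s[k])
      b <- idx_of(idle$end_s[k] - 1 / rate)
      if (i >= a && i <= b) return(c(a, b))
    }
    c(1L, n)
  }
  for (r in seq_len(nrow(runs))) {
    eb <- epoch_bounds(runs$start[r])
    i <- runs$start[r]
    while (i > eb[1] && z[i - 1L] > boundary_z) i <- i - 1L
    runs$start[r] <- i
    j <- runs$end[r]
    while (j < eb[2] && z[j + 1L] > boundary_z) j <- j + 1L
    runs$end[r] <- j
  }
  runs <- runs[order(runs$start), , drop = FALSE]
  runs <- merge_runs(runs, max_gap = max(1L, round(min_gap_ms / 1000 * rate)))
  dur_ms <- (runs$end - runs$start + 1L) / rate * 1000
  keep <- dur_ms >= min_dur_ms
  runs <- runs[keep, , drop = FALSE]
  dur_ms <- dur_ms[keep]
  if (!nrow(runs)) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      duration_ms = numeric(0), peak_z = numeric(0)))
  }
  out <- data.frame(
    start_s = (runs$start - 1L) / rate,
    end_s = runs$end / rate,
    duration_ms = dur_ms,
    peak_z = vapply(seq_len(nrow(runs)),
                    function(r) max(z[runs$start[r]:runs$end[r]]), 0))
  if (duration_method == "template") {
    off <- stats::median(s)
    for (r in seq_len(nrow(out))) {
      d <- fit_ripple_duration(s, xf1, runs$start[r], runs$end[r],
                               rate, band = c(band[1], hi),
                               sig_n = sig_n, off = off)
      if (!is.na(d)) out$duration_ms[r] <- d
    }
  }
  out
}

# Forward-model duration refit for one detected ripple. The smoothed
# squared envelope `s` in the event window (padded) is fitted with a
# Hann-envelope burst at the event's carrier frequency passed through the
# same band-pass / square / smooth chain. Returns the fitted support in
# ms, or NA when the fit is degenerate (e.g. it runs off the window).
fit_ripple_duration <- function(s, xf, i0, i1, rate, band, sig_n, off) {
  n <- length(s)
  seg <- xf[i0:i1]
  zc <- sum(diff(sign(seg)) != 0)
  fc <- zc / 2 / ((i1 - i0 + 1) / rate)
  fc <- min(max(fc, band[1] - 10), band[2] + 10)
  pad <- round(0.08 * rate)
  w <- max(1L, i0 - pad):min(n, i1 + pad)
  y <- sqrt(pmax(s[w], 0))
  tt <- (w - 1) / rate
  pk <- which.max(s[i0:i1]) + i0 - 1L
  obj <- function(par) {
    A <- par[1]
    t0 <- par[2]
    D <- exp(par[3])
    u <- (tt - t0) / D + 0.5
    henv <- ifelse(u > 0 & u < 1, sin(pi * u)^2, 0)
    fs <- butter_filtfilt(henv * sin(2 * pi * fc * (tt - t0)), rate,
                          band, "pass")
    m <- sqrt(pmax(A * gaussian_smooth(fs^2, sig_n), 0) + off)
    sum((y - m)^2)
  }
  D0 <- (i1 - i0 + 1) / rate
  fit <- tryCatch(
    stats::optim(c(max(s[w]) - off, (pk - 1) / rate, log(D0)), obj,
                 control = list(maxit = 500)),
    error = function(e) NULL)
  if (is.null(fit)) return(NA_real_)
  D <- exp(fit$par[3])
  if (D <= 0.005 || D > (length(w) / rate)) return(NA_real_)
  D * 1000
}

#' Ripple summary statistics
#'
#' Occurrence rate over the full idle time, arithmetic mean duration, and
#' the percentage of ripples lasting strictly more than 100 ms.
#'
#' @param events ripple table from [detect_ripples_kay()].
#' @param idle_epochs epoch table rows with `state == "idle"` (other rows
#'   are ignored); total idle duration must be positive.
#' @return data frame (`rate_hz`, `mean_duration_ms`, `pct_over_100ms`,
#'   `n_events`); duration statistics are `NA` when there are no events.
#' @export
ripple_stats <- function(events, idle_epochs) {
  idle <- idle_epochs[idle_epochs$state == "idle", , drop = FALSE]
  total <- sum(idle$end_s - idle$start_s)
  stopifnot(total > 0)
  n <- nrow(events)
  data.frame(
    rate_hz = n / total,
    mean_duration_ms = if (n) mean(events$duration_ms) else NA_real_,
    pct_over_100ms = if (n) 100 * mean(events$duration_ms > 100) else NA_real_,
    n_events = n)
}
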