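#' Detect extracellular spikes on every MEA channel
#'
#' Each channel is band-pass filtered, a robust per-channel noise SD
#' (MAD-based) is estimated on the filtered trace, and threshold crossings
#' of `threshold_k` SDs (either polarity) are reduced to one spike per
#' refractory window, timed at the absolute-peak sample.
#'
#' @param rec multichannel [recording()]; a rate below 10 kHz draws a
#'   warning because the upper band edge must then be clipped.
#' @param band_hz band-pass corners (Hz); the upper edge is clipped to
#'   80% of Nyquist.
#' @param threshold_k threshold in robust SDs.
#' @param refractory_ms minimum spike separation.
#' @return named list (by channel id) of numeric vectors of spike times (s).
#' @export
detect_spikes <- function(rec, band_hz = c(300, 3000), threshold_k = 4,
                          refractory_ms = 1) {
  stopifnot(inherits(rec, "recording"))
  if (ncol(rec$samples) == 0L) stop("empty recording")
  rate <- rec$rate_hz
  if (rate < 10000) warning("sampling rate below 10 kHz; band edge clipped")
  hi <- min(band_hz[2], 0.8 * rate / 2)
  ref_n <- max(1L, round(refractory_ms / 1000 * rate))
  out <- vector("list", n_channels(rec))
  names(out) <- rec$channel_ids
  for (ch in seq_len(n_channels(rec))) {
    xf <- butter_filtfilt(rec$samples[ch, ], rate, c(band_hz[1], hi), "pass",
                          order = 2L)
    thr <- threshold_k * robust_sd(xf)
    a <- abs(xf)
    above <- which(a > thr)
    times <- numeric(0)
    i <- 1L
    while (i <= length(above)) {
      i0 <- above[i]
      win <- i0:min(length(a), i0 + ref_n - 1L)
      pk <- win[which.max(a[win])]
      times <- c(times, (pk - 1L) / rate)
      nxt <- pk + ref_n
      while (i <= length(above) && above[i] < nxt) i <- i + 1L
    }
    out[[ch]] <- times
  }
  out
}

#' Poisson surprise of a spike cluster
#'
#' The surprise of observing `n` spikes in `t` seconds from a process with
#' mean rate `lambda` is `S = -log10 P(N >= n)` for `N ~ Poisson(lambda*t)`,
#' computed via the log-scale upper tail for numerical stability. `n = 0`
#' gives `S = 0`; `lambda = 0` with `n > 0` gives `Inf`.
#'
#' @param n spike count (>= 0).
#' @param t interval length in seconds (> 0).
#' @param lambda mean rate in Hz (>= 0).
#' @return the surprise S (dimensionless, >= 0).
#' @export
poisson_surprise <- function(n, t, lambda) {
  stopifnot(t > 0, lambda >= 0, n >= 0)
  if (n == 0) return(0)
  if (lambda == 0) return(Inf)
  lp <- stats::ppois(n - 1, lambda * t, lower.tail = FALSE, log.p = TRUE)
  -lp / log(10)
}

#' Detect bursts in a spike train by the Poisson-surprise method
#'
#' Candidate bursts are maximal runs of inter-spike intervals shorter than
#' half the train's mean ISI; each candidate is greedily extended at either
#' end while the surprise increases, then trimmed likewise. A burst is
#' accepted when `S >= s_min`, it has at least `min_spikes` spikes and lasts
#' at least `min_dur_s`. Bursts never overlap.
#'
#' @param times sorted spike times (s) of one channel.
#' @param train_duration_s recording length used to estimate the mean rate.
#' @param s_min minimum surprise (default 10, a common analysis default).
#' @param min_spikes minimum spikes per burst (default 10).
#' @param min_dur_s minimum burst duration in seconds (default 0.1).
#' @return data frame (`start_s`, `end_s`, `n_spikes`, `surprise`).
#' @export
detect_bursts <- function(times, train_duration_s, s_min = 10,
                          min_spikes = 10, min_dur_s = 0.1) {
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      n_spikes = integer(0), surprise = numeric(0))
  n <- length(times)
  if (n < 2L) return(empty)
  stopifnot(train_duration_s > 0, !is.unsorted(times))
  lambda <- n / train_duration_s
  isi <- diff(times)
  isi_thr <- 0.5 * mean(isi)

  surprise_of <- function(i, j) {
    dt <- times[j] - times[i]
    if (dt <= 0) dt <- 1 / 1e6
    poisson_surprise(j - i + 1L, dt, lambda)
  }

  runs <- true_runs(isi < isi_thr)   # run k covers spikes start..end+1
  out <- list()
  last_end <- 0L
  for (k in seq_len(nrow(runs))) {
    i <- runs$start[k]
    j <- runs$end[k] + 1L
    if (i <= last_end) i <- last_end + 1L
    if (j - i + 1L < 2L) next
    s <- surprise_of(i, j)
    repeat {                         # extend while surprise increases
      improved <- FALSE
      if (j < n) {
        s2 <- surprise_of(i, j + 1L)
        if (s2 > s) { j <- j + 1L; s <- s2; improved <- TRUE }
      }
      if (i > last_end + 1L) {
        s2 <- surprise_of(i - 1L, j)
        if (s2 > s) { i <- i - 1L; s <- s2; improved <- TRUE }
      }
      if (!improved) break
    }
    repeat {                         # trim while surprise increases
      improved <- FALSE
      if (j - i + 1L > 2L) {
        s2 <- surprise_of(i + 1L, j)
        if (s2 > s) { i <- i + 1L; s <- s2; improved <- TRUE }
        if (j - i + 1L > 2L) {
          s2 <- surprise_of(i, j - 1L)
          if (s2 > s) { j <- j - 1L; s <- s2; improved <- TRUE }
        }
      }
      if (!improved) break
    }
    dur <- times[j] - times[i]
    if (s >= s_min && (j - i + 1L) >= min_spikes && dur >= min_dur_s) {
      out[[length(out) + 1L]] <- data.frame(
        start_s = times[i], end_s = times[j],
        n_spikes = j - i + 1L, surprise = s)
      last_end <- j
    }
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Preprocess an MEA recording for cluster analysis
#'
#' Anti-aliased decimation to `target_hz` (default 5 kHz; the original
#' rate must be an integer multiple), then per-channel demeaning with a
#' 1 s window at 50% overlap: window means are computed at centers every
#' 0.5 s and linearly interpolated between them before subtraction, so
#' slow drift is removed while fast transients pass.
#'
#' @param rec multichannel [recording()], rate >= 5 kHz.
#' @param target_hz output rate.
#' @param window_s demeaning window length.
#' @return a [recording()] at `target_hz`, demeaned.
#' @export
preprocess_for_clusters <- function(rec, target_hz = 5000, window_s = 1) {
  stopifnot(inherits(rec, "recording"))
  rate <- rec$rate_hz
  if (rate < target_hz) stop("sampling rate below the 5 kHz target")
  r <- rate / target_hz
  if (abs(r - round(r)) > 1e-9) {
    stop("sampling rate must be an integer multiple of the target rate")
  }
  r <- as.integer(round(r))
  x <- rec$samples
  if (r > 1L) {
    cut_hz <- 0.8 * target_hz / 2
    keep <- seq(1L, ncol(x), by = r)
    y <- matrix(0, nrow = nrow(x), ncol = length(keep))
    for (ch in seq_len(nrow(x))) {
      y[ch, ] <- butter_filtfilt(x[ch, ], rate, cut_hz, "low")[keep]
    }
    x <- y
  }
  n <- ncol(x)
  win_n <- round(window_s * target_hz)
  if (n < win_n) {
    warning("recording shorter than the demeaning window; single-window demeaning")
    x <- x - rowMeans(x)
  } else {
    step <- win_n %/% 2L
    starts <- seq(1L, n - win_n + 1L, by = step)
    centers <- starts + (win_n - 1L) / 2
    for (ch in seq_len(nrow(x))) {
      mu <- vapply(starts, function(s) mean(x[ch, s:(s + win_n - 1L)]), 0)
      base <- interp_extrap(centers, mu, n)
      x[ch, ] <- x[ch, ] - base
    }
  }
  recording(x, target_hz, channel_ids = rec$channel_ids,
            geometry = rec$geometry, units = rec$units)
}

#' Largest 8-connected component of a logical grid mask
#'
#' Iterative flood fill over TRUE cells with 8-connectivity (the 2-D
#' default of standard connected-component labelling).
#'
#' @param mask logical matrix.
#' @return size of the largest connected component (0 for an empty mask).
#' @export
max_cluster_size <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  best <- 0L
  nxt <- 0L
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (!mask[r0, c0] || lab[r0, c0] != 0L) next
    nxt <- nxt + 1L
    stack <- list(c(r0, c0))
    lab[r0, c0] <- nxt
    size <- 0L
    while (length(stack)) {
      cell <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      size <- size + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- cell[1] + dr; cc <- cell[2] + dc
        if (rr >= 1L && rr <= nr && cc >= 1L && cc <= nc &&
            mask[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- nxt
          stack[[length(stack) + 1L]] <- c(rr, cc)
        }
      }
    }
    if (size > best) best <- size
  }
  best
}

# Per-channel SD of the preprocessed recording (the cluster thresholds).
channel_sds <- function(rec5k) apply(rec5k$samples, 1, stats::sd)

# Map a sample vector onto the grid given the recording geometry.
grid_matrix <- function(values, geometry) {
  nr <- max(geometry$row); nc <- max(geometry$col)
  m <- matrix(NA_real_, nr, nc)
  m[cbind(geometry$row, geometry$col)] <- values
  m
}

#' Largest activity clusters at one time point
#'
#' At the sample nearest `t`, channels whose value exceeds `+k` (positive
#' cluster) or falls below `-k` (negative cluster) times their SD are
#' marked on the grid; the largest 8-connected component size is returned
#' for each polarity.
#'
#' @param rec5k preprocessed [recording()] with full grid geometry.
#' @param t time (s), inside the recording.
#' @param sds per-channel SDs; defaults to the SD of each channel over the
#'   whole recording.
#' @param threshold_k threshold in SD units (default 2).
#' @return list `(max_pos, max_neg)`.
#' @export
activity_clusters_at <- function(rec5k, t, sds = NULL, threshold_k = 2) {
  stopifnot(inherits(rec5k, "recording"))
  if (is.null(rec5k$geometry)) stop("recording has no grid geometry")
  i <- round(t * rec5k$rate_hz) + 1L
  if (i < 1L || i > ncol(rec5k$samples)) stop("t outside the recording")
  if (is.null(sds)) sds <- channel_sds(rec5k)
  v <- rec5k$samples[, i]
  pos <- grid_matrix(as.numeric(v > threshold_k * sds), rec5k$geometry) == 1
  neg <- grid_matrix(as.numeric(v < -threshold_k * sds), rec5k$geometry) == 1
  pos[is.na(pos)] <- FALSE
  neg[is.na(neg)] <- FALSE
  list(max_pos = max_cluster_size(pos), max_neg = max_cluster_size(neg))
}

#' Cluster-size timecourse around dentate-gyrus trigger spikes
#'
#' For each trigger spike, the largest spatially adjacent cluster size is
#' evaluated on a grid of 21 lags at 5 ms spacing; the per-bin scalar is
#' the larger of the positive- and negative-polarity maximal clusters.
#' The default grid spans 0..100 ms after the spike; `centered = TRUE`
#' restores a -50..+50 ms grid around it. Curves are normalized to the
#' mean of the first 4 bins following the spike (lags 0-15 ms). Triggers
#' whose window leaves the recording are skipped.
#'
#' @param rec5k preprocessed [recording()] with grid geometry (see
#'   [preprocess_for_clusters()]).
#' @param dg_spike_times trigger spike times (s).
#' @param threshold_k cluster threshold in SD units.
#' @param centered use the spike-centered lag grid instead of post-spike.
#' @return list with `per_trigger` (long data frame: `trigger_t`,
#'   `lag_ms`, `raw`, `normalized`, `polarity_used`), `mean_curve`
#'   (`lag_ms`, `raw`, `normalized`), and `summary` (`max_first_20ms`,
#'   `norm_mean_30_70ms`, `n_triggers`).
#' @export
cluster_timecourse <- function(rec5k, dg_spike_times, threshold_k = 2,
                               centered = FALSE) {
  lags_ms <- if (centered) seq(-50, 50, by = 5) else seq(0, 100, by = 5)
  sds <- channel_sds(rec5k)
  n <- ncol(rec5k$samples)
  rows <- list()
  for (tt in dg_spike_times) {
    i_all <- round((tt + lags_ms / 1000) * rec5k$rate_hz) + 1L
    if (any(i_all < 1L | i_all > n)) next   # trigger too close to an edge
    raw <- numeric(length(lags_ms))
    pol <- character(length(lags_ms))
    for (b in seq_along(lags_ms)) {
      cl <- activity_clusters_at(rec5k, tt + lags_ms[b] / 1000, sds = sds,
                                 threshold_k = threshold_k)
      raw[b] <- max(cl$max_pos, cl$max_neg)
      pol[b] <- if (cl$max_pos >= cl$max_neg) "positive" else "negative"
    }
    first4 <- mean(raw[lags_ms >= 0 & lags_ms <= 15])
    rows[[length(rows) + 1L]] <- data.frame(
      trigger_t = tt, lag_ms = lags_ms, raw = raw,
      normalized = if (first4 > 0) raw / first4 else NA_real_,
      polarity_used = pol)
  }
  if (!length(rows)) {
    return(list(per_trigger = data.frame(), mean_curve = data.frame(),
                summary = data.frame(max_first_20ms = NA_real_,
                                     norm_mean_30_70ms = NA_real_,
                                     n_triggers = 0L)))
  }
  per_trigger <- do.call(rbind, rows)
  mean_raw <- tapply(per_trigger$raw, per_trigger$lag_ms, mean)
  lag_grid <- as.numeric(names(mean_raw))
  o <- order(lag_grid)
  lag_grid <- lag_grid[o]
  mean_raw <- as.numeric(mean_raw)[o]
  first4 <- mean(mean_raw[lag_grid >= 0 & lag_grid <= 15])
  mean_curve <- data.frame(
    lag_ms = lag_grid, raw = mean_raw,
    normalized = if (first4 > 0) mean_raw / first4 else NA_real_)
  in_2070 <- lag_grid >= 30 & lag_grid <= 70
  summary <- data.frame(
    max_first_20ms = max(mean_raw[lag_grid >= 0 & lag_grid <= 20]),
    norm_mean_30_70ms = mean(mean_curve$normalized[in_2070]),
    n_triggers = length(rows))
  list(per_trigger = per_trigger, mean_curve = mean_curve, summary = summary)
}
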