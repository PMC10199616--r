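#' Robust baseline RMS noise of a voltage-clamp trace
#'
#' Estimates the event-free noise scale: the trace is high-passed above
#' `hp_hz` to strip synaptic events and slow envelopes, the scale is taken
#' as MAD/0.6745 of the residual, and the value is corrected for the power
#' removed by the filter assuming a white noise floor, so pure white noise
#' is estimated without bias. Returns 0 for a constant trace.
#'
#' @param trace single-channel [recording()] or numeric vector.
#' @param rate_hz sampling rate; taken from the recording when omitted.
#' @param hp_hz high-pass corner (Hz); clipped below Nyquist.
#' @return noise RMS in the trace's units.
#' @export
estimate_rms_noise <- function(trace, rate_hz = NULL, hp_hz = 1000) {
  x <- as_trace(trace)
  rate_hz <- rate_hz %||% attr(x, "rate_hz")
  if (is.null(rate_hz)) stop("rate_hz required for a bare vector")
  if (length(x) < rate_hz) stop("need at least 1 s of data")
  if (stats::sd(x) == 0) return(0)
  hp <- min(hp_hz, 0.8 * rate_hz / 2)
  xf <- butter_filtfilt(x, rate_hz, hp, "high")
  est <- robust_sd(xf)
  # white-noise gain of the filter: fraction of flat-spectrum RMS retained
  fr <- signal::freqz(signal::butter(4, hp / (rate_hz / 2), "high"),
                      n = 512)
  g <- sqrt(mean(abs(fr$h)^2))
  est / g
}

as_trace <- function(trace) {
  if (inherits(trace, "recording")) {
    if (nrow(trace$samples) != 1L) stop("expected a single-channel trace")
    x <- trace$samples[1L, ]
    attr(x, "rate_hz") <- trace$rate_hz
    return(x)
  }
  as.numeric(trace)
}

#' Detect spontaneous synaptic events in a voltage-clamp trace
#'
#' Deviations from a local running-median baseline that exceed
#' `threshold_k` times the baseline RMS noise are detected as events:
#' outward (positive; IPSC under a low-chloride internal at -50 mV) or
#' inward (negative; EPSC). The deviation signal is lightly smoothed
#' (boxcar, `smooth_ms`) before peak picking so single noise samples do
#' not trigger; candidate peaks closer than `refractory_ms` are merged to
#' the larger. Reported amplitude is the smoothed deviation at the peak.
#'
#' @param trace single-channel [recording()].
#' @param noise_rms baseline RMS noise (pA); computed by
#'   [estimate_rms_noise()] when `NULL`.
#' @param threshold_k threshold in multiples of `noise_rms` (default 2,
#'   the conventional criterion for spontaneous PSCs).
#' @param baseline_ms running-median detection-baseline window (ms). It
#'   must be wide relative to a single PSC so the median is not dragged
#'   by the event itself (which would fabricate opposite-polarity
#'   undershoots); 200 ms is safe for PSC decay constants of 10-20 ms.
#' @param pre_event_ms window before each event over which the reported
#'   `local_baseline_pa` (median of the raw trace) is computed.
#' @param smooth_ms boxcar smoothing of the deviation signal (ms).
#' @param refractory_ms merge window for nearby candidate peaks (ms).
#' @return data frame (`t_s`, `polarity`, `amplitude_pa`,
#'   `local_baseline_pa`), times sorted, amplitudes positive.
#' @export
detect_events <- function(trace, noise_rms = NULL, threshold_k = 2,
                          baseline_ms = 200, pre_event_ms = 50,
                          smooth_ms = 2, refractory_ms = 5) {
  x <- as_trace(trace)
  rate <- attr(x, "rate_hz")
  if (length(x) == 0L) stop("zero-length trace")
  if (is.null(noise_rms)) noise_rms <- estimate_rms_noise(trace)
  if (noise_rms <= 0) noise_rms <- .Machine$double.eps
  thr <- threshold_k * noise_rms

  k_base <- max(3L, round(baseline_ms / 1000 * rate))
  if (k_base %% 2L == 0L) k_base <- k_base + 1L
  ref_n <- max(1L, round(refractory_ms / 1000 * rate))

  find_side <- function(d, polarity) {
    runs <- true_runs(d > thr)
    if (nrow(runs)) runs <- merge_runs(runs, max_gap = ref_n)
    idx <- integer(0)
    for (r in seq_len(nrow(runs))) {
      seg <- d[runs$start[r]:runs$end[r]]
      pk <- local_maxima_above(c(-Inf, seg, -Inf), thr) - 1L
      if (!length(pk)) pk <- which.max(seg)
      # split overlapping events: keep an additional maximum only when it
      # is beyond the refractory window and separated by a trough whose
      # prominence (drop below both peaks) is at least one threshold, so
      # noise wiggles along a decay never count twice but genuinely
      # stacked events (including bursts' nested events) do
      acc <- pk[1L]
      if (length(pk) > 1L) {
        for (k in 2L:length(pk)) {
          last <- acc[length(acc)]
          trough <- min(seg[last:pk[k]])
          if (pk[k] - last >= ref_n &&
              trough < min(seg[last], seg[pk[k]]) - thr) {
            acc <- c(acc, pk[k])
          } else if (seg[pk[k]] > seg[last]) {
            acc[length(acc)] <- pk[k]
          }
        }
      }
      idx <- c(idx, runs$start[r] - 1L + acc)
    }
    if (!length(idx)) {
      return(data.frame(t_s = numeric(0), polarity = character(0),
                        amplitude_pa = numeric(0),
                        local_baseline_pa = numeric(0)))
    }
    pre_n <- max(1L, round(pre_event_ms / 1000 * rate))
    pre_base <- vapply(idx, function(i) {
      stats::median(x[max(1L, i - pre_n):max(1L, i - 1L)])
    }, 0)
    data.frame(t_s = (idx - 1L) / rate, polarity = polarity,
               amplitude_pa = d[idx], local_baseline_pa = pre_base)
  }

  smooth_dev <- function(v) boxcar_smooth(v, round(smooth_ms / 1000 * rate))

  # The baseline has two components.
  #
  # (1) A *flat* component estimated on a long (10x baseline_ms) window so
  # that neither event clusters nor slow network bursts can drag it: the
  # initial long running median is refined twice by masking every sample
  # whose deviation is event-like (above half threshold, padded beyond
  # the decay) and taking the median of the unmasked samples per window,
  # interpolated between window centers.
  #
  # (2) A *slow envelope* component: the running median (baseline_ms) of
  # the flat-corrected trace tracks slow outward currents but not the
  # fast events riding on them; where it stays above threshold for at
  # least 80 ms (a network burst; single PSCs are far shorter) it is
  # subtracted, so nested events stay detectable and burst edges do not
  # masquerade as events of either polarity.
  n <- length(x)
  k_long <- min(10L * k_base, if (n %% 2L == 0L) n - 1L else n)
  if (k_long %% 2L == 0L) k_long <- k_long - 1L
  baseline <- stats::runmed(x, k_long, endrule = "median")
  pre_pad <- max(1L, round(0.005 * rate))
  post_pad <- max(1L, round(0.030 * rate))
  if (n > k_long) {
    for (pass in 1:2) {
      dev0 <- smooth_dev(x - baseline)
      hot <- true_runs(abs(dev0) > 0.5 * thr)
      if (!nrow(hot)) break
      mask <- rep(FALSE, n)
      for (r in seq_len(nrow(hot))) {
        mask[max(1L, hot$start[r] - pre_pad):min(n, hot$end[r] + post_pad)] <- TRUE
      }
      if (all(mask)) break
      step <- (k_long - 1L) %/% 2L
      starts <- seq(1L, n - k_long + 1L, by = step)
      centers <- starts + (k_long - 1L) / 2
      mu <- vapply(starts, function(s) {
        w <- s:(s + k_long - 1L)
        w <- w[!mask[w]]
        if (length(w) >= 100L) stats::median(x[w]) else NA_real_
      }, 0)
      if (!any(!is.na(mu))) break
      ok <- !is.na(mu)
      baseline <- stats::approx(centers[ok], mu[ok], xout = seq_len(n),
                                rule = 2)$y
    }
  }

  # No slow-envelope subtraction: a network burst simply becomes one long
  # supra-threshold outward run relative to the flat baseline, and its
  # nested events are recovered by the prominence-based peak splitting.
  dev <- smooth_dev(x - baseline)
  ev <- rbind(find_side(dev, "outward"), find_side(-dev, "inward"))
  ev <- ev[order(ev$t_s), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Detect slow outward network bursts
#'
#' Isolates the slow outward envelope with a running median over
#' `slow_window_ms` (a median, unlike a low-pass filter, is insensitive
#' to the fast synaptic events riding on the burst), then keeps episodes
#' whose envelope peak exceeds `min_amp_pa` above baseline and whose
#' supra-half-threshold extent lasts at least `min_dur_ms`; episodes
#' separated by less than `merge_gap_ms` are joined before the rules are
#' applied. Both acceptance criteria (>= 10 pA, >= 100 ms) hold for every
#' returned burst by construction.
#'
#' @param trace single-channel [recording()] (pA).
#' @param min_amp_pa minimum peak amplitude above baseline (default 10).
#' @param min_dur_ms minimum duration at half of `min_amp_pa` (default 100).
#' @param slow_window_ms running-median window isolating the slow
#'   envelope (default 200 ms; bursts much shorter than this are
#'   attenuated, but the duration rule discards those anyway).
#' @param merge_gap_ms sub-threshold gaps shorter than this are bridged.
#' @return data frame (`onset_s`, `duration_s`, `peak_amplitude_pa`).
#' @export
detect_network_bursts <- function(trace, min_amp_pa = 10, min_dur_ms = 100,
                                  slow_window_ms = 200, merge_gap_ms = 100) {
  x <- as_trace(trace)
  rate <- attr(x, "rate_hz")
  if (length(x) == 0L) stop("zero-length trace")
  k <- max(3L, round(slow_window_ms / 1000 * rate))
  if (k %% 2L == 0L) k <- k + 1L
  slow <- stats::runmed(x, k, endrule = "median")
  slow <- slow - stats::median(slow)
  half <- min_amp_pa / 2
  runs <- true_runs(slow > half)
  if (nrow(runs) == 0L) {
    return(data.frame(onset_s = numeric(0), duration_s = numeric(0),
                      peak_amplitude_pa = numeric(0)))
  }
  runs <- merge_runs(runs, max_gap = round(merge_gap_ms / 1000 * rate))
  out <- lapply(seq_len(nrow(runs)), function(i) {
    seg <- slow[runs$start[i]:runs$end[i]]
    dur_s <- (runs$end[i] - runs$start[i] + 1L) / rate
    peak <- max(seg)
    if (peak >= min_amp_pa && dur_s >= min_dur_ms / 1000) {
      data.frame(onset_s = (runs$start[i] - 1L) / rate,
                 duration_s = dur_s, peak_amplitude_pa = peak)
    }
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(onset_s = numeric(0), duration_s = numeric(0),
                      peak_amplitude_pa = numeric(0))
  }
  rownames(out) <- NULL
  out
}

#' Summarize a cell's detected activity with inclusion rules
#'
#' Computes per-polarity event frequencies and mean amplitudes plus the
#' network-burst frequency, and applies the standard inclusion criteria:
#' a cell is excluded when any analyzed event class has frequency below
#' `min_freq_hz` (0.008 Hz, i.e. 0.5 events/min), or, when series-
#' resistance metadata is given, when Rs >= 30 MOhm at the start or Rs
#' changed by more than 20%. A warning is raised when both fewer than
#' 200 events and less than 5 min of data were analyzed.
#'
#' @param events event table from [detect_events()].
#' @param bursts burst table from [detect_network_bursts()] (optional).
#' @param analyzed_duration_s analyzed time (s), > 0.
#' @param cell_id label.
#' @param rs_start_mohm,rs_change_frac optional series-resistance metadata.
#' @param min_freq_hz exclusion threshold (default 0.008).
#' @param exclusion_per_polarity apply the frequency rule to each polarity
#'   separately (default) or to the total event frequency.
#' @return one-row data frame (class `cell_summary`): `cell_id`,
#'   `freq_outward_hz`, `freq_inward_hz`, `amp_outward_pa`,
#'   `amp_inward_pa`, `burst_freq_hz`, `included`.
#' @export
summarize_cell <- function(events, bursts = NULL, analyzed_duration_s,
                           cell_id = "cell1", rs_start_mohm = NA,
                           rs_change_frac = NA, min_freq_hz = 0.008,
                           exclusion_per_polarity = TRUE) {
  stopifnot(analyzed_duration_s > 0)
  n_out <- sum(events$polarity == "outward")
  n_in <- sum(events$polarity == "inward")
  if (n_out + n_in < 200 && analyzed_duration_s < 300) {
    warning("fewer than 200 events and less than 5 min analyzed")
  }
  f_out <- n_out / analyzed_duration_s
  f_in <- n_in / analyzed_duration_s
  freqs <- if (exclusion_per_polarity) c(f_out, f_in) else
    (n_out + n_in) / analyzed_duration_s
  included <- all(freqs >= min_freq_hz)
  if (!is.na(rs_start_mohm) && rs_start_mohm >= 30) included <- FALSE
  if (!is.na(rs_change_frac) && rs_change_frac > 0.20) included <- FALSE
  out <- data.frame(
    cell_id = cell_id,
    freq_outward_hz = f_out, freq_inward_hz = f_in,
    amp_outward_pa = if (n_out) mean(events$amplitude_pa[events$polarity == "outward"]) else NA_real_,
    amp_inward_pa = if (n_in) mean(events$amplitude_pa[events$polarity == "inward"]) else NA_real_,
    burst_freq_hz = if (is.null(bursts)) NA_real_ else
      nrow(bursts) / analyzed_duration_s,
    included = included)
  class(out) <- c("cell_summary", class(out))
  out
}

#' Baseline-normalized drug effect for one cell
#'
#' Ratio of each measure during drug application over baseline, the form
#' used for graphical summaries; the raw paired values are retained so
#' that statistical tests run on raw data. A measure with zero baseline
#' yields `NA` with `defined = FALSE`.
#'
#' @param baseline,drug `cell_summary` rows from [summarize_cell()] for the
#'   same cell; both must be `included`.
#' @return data frame (`measure`, `baseline`, `drug`, `ratio`, `defined`).
#' @export
drug_effect <- function(baseline, drug) {
  if (baseline$cell_id != drug$cell_id) {
    stop("baseline and drug summaries are from different cells")
  }
  if (!baseline$included || !drug$included) {
    stop("both conditions must pass the inclusion criteria")
  }
  measures <- c("freq_outward_hz", "freq_inward_hz",
                "amp_outward_pa", "amp_inward_pa", "burst_freq_hz")
  b <- as.numeric(baseline[1, measures])
  d <- as.numeric(drug[1, measures])
  ratio <- ifelse(!is.na(b) & b > 0, d / b, NA_real_)
  data.frame(measure = measures, baseline = b, drug = d, ratio = ratio,
             defined = !is.na(ratio))
}
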