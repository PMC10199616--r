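#' Parameters for the voltage-clamp trace simulator
#'
#' Defaults describe a neonatal CA3 pyramidal-cell recording under a
#' low-chloride internal solution at -50 mV: GABAergic events (IPSCs) are
#' outward (positive) and glutamatergic events (EPSCs) inward (negative).
#' Event rates default to the magnitudes typical of such recordings
#' (IPSCs a few Hz, EPSCs a fraction of a Hz); amplitudes are drawn from a
#' truncated normal; kinetics are a difference of exponentials.
#'
#' @param rate_ipsc_hz,rate_epsc_hz Poisson rates of outward / inward events.
#' @param amp_mean_pa,amp_sd_pa amplitude distribution (pA), per event,
#'   truncated below at `0.2 * amp_mean_pa`.
#' @param rise_ms,decay_ms bi-exponential kinetics; `decay_ms > rise_ms`.
#' @param burst_rate_hz,burst_amp_pa,burst_dur_ms slow outward network-burst
#'   envelope: Poisson rate, plateau amplitude and plateau duration.
#' @param burst_ipsc_gain multiplicative boost of the IPSC rate inside a
#'   burst (bursts nest fast GABAergic events).
#' @param noise_rms_pa white-noise RMS (pA).
#' @param duration_s,rate_hz trace length and sampling rate.
#' @param seed RNG seed (mandatory; a simulation is a pure function of its
#'   parameters).
#' @return a `patch_sim_params` list.
#' @export
patch_sim_params <- function(rate_ipsc_hz = 4, rate_epsc_hz = 0.25,
                             amp_mean_pa = 20, amp_sd_pa = 5,
                             rise_ms = 1.5, decay_ms = 12,
                             burst_rate_hz = 0.034, burst_amp_pa = 20,
                             burst_dur_ms = 500, burst_ipsc_gain = 3,
                             noise_rms_pa = 2, duration_s = 300,
                             rate_hz = 5000, seed = 1L) {
  p <- list(rate_ipsc_hz = rate_ipsc_hz, rate_epsc_hz = rate_epsc_hz,
            amp_mean_pa = amp_mean_pa, amp_sd_pa = amp_sd_pa,
            rise_ms = rise_ms, decay_ms = decay_ms,
            burst_rate_hz = burst_rate_hz, burst_amp_pa = burst_amp_pa,
            burst_dur_ms = burst_dur_ms, burst_ipsc_gain = burst_ipsc_gain,
            noise_rms_pa = noise_rms_pa, duration_s = duration_s,
            rate_hz = rate_hz, seed = as.integer(seed))
  stopifnot(p$rate_ipsc_hz >= 0, p$rate_epsc_hz >= 0, p$burst_rate_hz >= 0,
            p$decay_ms > p$rise_ms, p$noise_rms_pa >= 0,
            p$duration_s > 0, p$rate_hz > 0)
  class(p) <- "patch_sim_params"
  p
}

#' Unit-peak postsynaptic-current kernel
#'
#' Difference of exponentials `exp(-t/tau_d) - exp(-t/tau_r)` normalized to
#' unit peak. The peak occurs at
#' `t = tau_r * tau_d / (tau_d - tau_r) * log(tau_d / tau_r)`.
#'
#' @param t_s time from onset (s), vector; values < 0 give 0.
#' @param rise_ms,decay_ms kinetics in ms.
#' @return kernel values, peak exactly 1.
#' @export
psc_kernel <- function(t_s, rise_ms, decay_ms) {
  tr <- rise_ms / 1000
  td <- decay_ms / 1000
  tpk <- tr * td / (td - tr) * log(td / tr)
  peak <- exp(-tpk / td) - exp(-tpk / tr)
  k <- ifelse(t_s < 0, 0, (exp(-t_s / td) - exp(-t_s / tr)) / peak)
  k
}

#' Peak latency of the PSC kernel
#' @inheritParams psc_kernel
#' @return time to peak in seconds.
#' @export
psc_peak_time_s <- function(rise_ms, decay_ms) {
  tr <- rise_ms / 1000
  td <- decay_ms / 1000
  tr * td / (td - tr) * log(td / tr)
}

# Plateau envelope with raised-cosine (Hann) edges. Plateau of `plateau_s`
# at unit amplitude, edges of `edge_s` each side; support = plateau + 2 edges.
plateau_envelope <- function(t_s, plateau_s, edge_s) {
  total <- plateau_s + 2 * edge_s
  e <- numeric(length(t_s))
  inside <- t_s >= 0 & t_s <= total
  tt <- t_s[inside]
  v <- rep(1, length(tt))
  up <- tt < edge_s
  v[up] <- 0.5 * (1 - cos(pi * tt[up] / edge_s))
  dn <- tt > edge_s + plateau_s
  v[dn] <- 0.5 * (1 + cos(pi * (tt[dn] - edge_s - plateau_s) / edge_s))
  e[inside] <- v
  e
}

#' Simulate a voltage-clamp current trace with known ground truth
#'
#' Generates a single-channel trace in pA: Poisson trains of outward
#' (IPSC, positive) and inward (EPSC, negative) bi-exponential events,
#' slow outward network-burst envelopes with a nested boost of the IPSC
#' rate, and additive Gaussian white noise.
#'
#' @param p a [patch_sim_params()].
#' @return list with elements `recording` (1-channel [recording()], units
#'   pA), and `truth` — a list with `events` (`t_s`, `polarity`,
#'   `amplitude_pa`), `bursts` (`onset_s`, `duration_s`,
#'   `peak_amplitude_pa`) and the echoed `params`. `t_s` is event onset;
#'   the trace peaks `psc_peak_time_s()` later.
#' @export
gen_patch_trace <- function(p) {
  stopifnot(inherits(p, "patch_sim_params"))
  set.seed(p$seed)
  n <- round(p$duration_s * p$rate_hz)
  x <- numeric(n)
  dt <- 1 / p$rate_hz

  # network bursts first (their windows boost the IPSC rate)
  edge_s <- 0.1 * p$burst_dur_ms / 1000 + 0.025
  n_b <- stats::rpois(1, p$burst_rate_hz * p$duration_s)
  bursts <- data.frame(onset_s = numeric(0), duration_s = numeric(0),
                       peak_amplitude_pa = numeric(0))
  if (n_b > 0) {
    onset <- sort(stats::runif(n_b, 0, max(0, p$duration_s - p$burst_dur_ms / 1000 - 2 * edge_s)))
    bursts <- data.frame(onset_s = onset,
                         duration_s = rep(p$burst_dur_ms / 1000 + 2 * edge_s, n_b),
                         peak_amplitude_pa = rep(p$burst_amp_pa, n_b))
    for (i in seq_len(n_b)) {
      i0 <- floor(onset[i] * p$rate_hz) + 1L
      len <- ceiling((p$burst_dur_ms / 1000 + 2 * edge_s) * p$rate_hz) + 1L
      idx <- i0:min(n, i0 + len - 1L)
      tt <- (idx - i0) * dt
      x[idx] <- x[idx] + p$burst_amp_pa *
        plateau_envelope(tt, p$burst_dur_ms / 1000, edge_s)
    }
  }

  in_burst <- function(t) {
    if (nrow(bursts) == 0) return(rep(FALSE, length(t)))
    res <- rep(FALSE, length(t))
    for (i in seq_len(nrow(bursts))) {
      res <- res | (t >= bursts$onset_s[i] &
                    t < bursts$onset_s[i] + bursts$duration_s[i])
    }
    res
  }

  draw_events <- function(rate, polarity) {
    # thinning: base rate everywhere, boosted inside bursts
    gain <- if (polarity == "outward") p$burst_ipsc_gain else 1
    rmax <- rate * max(1, gain)
    n_e <- stats::rpois(1, rmax * p$duration_s)
    if (n_e == 0 || rate == 0) {
      return(data.frame(t_s = numeric(0), polarity = character(0),
                        amplitude_pa = numeric(0)))
    }
    t <- sort(stats::runif(n_e, 0, p$duration_s))
    acc_p <- ifelse(in_burst(t), gain * rate / rmax, rate / rmax)
    keep <- stats::runif(n_e) < acc_p
    t <- t[keep]
    amp <- stats::rnorm(length(t), p$amp_mean_pa, p$amp_sd_pa)
    amp <- pmax(amp, 0.2 * p$amp_mean_pa)
    data.frame(t_s = t, polarity = rep(polarity, length(t)),
               amplitude_pa = amp)
  }

  ev <- rbind(draw_events(p$rate_ipsc_hz, "outward"),
              draw_events(p$rate_epsc_hz, "inward"))
  ev <- ev[order(ev$t_s), , drop = FALSE]
  rownames(ev) <- NULL

  if (nrow(ev) > 0) {
    k_len <- ceiling((p$decay_ms / 1000 * 8) * p$rate_hz)
    k_t <- (0:(k_len - 1L)) * dt
    k <- psc_kernel(k_t, p$rise_ms, p$decay_ms)
    for (i in seq_len(nrow(ev))) {
      i0 <- floor(ev$t_s[i] * p$rate_hz) + 1L
      idx <- i0:min(n, i0 + k_len - 1L)
      s <- if (ev$polarity[i] == "outward") 1 else -1
      x[idx] <- x[idx] + s * ev$amplitude_pa[i] * k[seq_along(idx)]
    }
  }

  if (p$noise_rms_pa > 0) x <- x + stats::rnorm(n, 0, p$noise_rms_pa)

  list(
    recording = recording(x, p$rate_hz, channel_ids = "cell1", units = "pA"),
    truth = list(events = ev, bursts = bursts, params = p)
  )
}

#' Parameters for the 8x8 MEA simulator
#'
#' Emulates an organotypic hippocampal slice on a 64-electrode grid:
#' per-channel background spiking, optional burst episodes, large
#' dentate-gyrus (DG) trigger spikes on a designated channel, and a
#' propagating activity wave recruited after each DG spike. The wave
#' recruits `wave_extent` channels outward from `wave_origin` in
#' 8-connected rings, one channel every `1/wave_speed` ms, each staying
#' depolarized (plateau deflection of `wave_amp_sd` noise SDs) for
#' `wave_hold_ms`.
#'
#' @param baseline_rate_hz background spike rate per channel.
#' @param burst_rate_hz,burst_n_spikes,burst_dur_s burst episodes per
#'   channel: rate, spikes per episode (>= 10 to satisfy the burst rule),
#'   episode duration (>= 0.1 s).
#' @param dg_spike_times explicit DG trigger times (s), or `NULL` to draw
#'   them as Poisson at `dg_spike_rate_hz` (with a 0.3 s refractory and a
#'   0.2 s margin from the recording edges).
#' @param dg_spike_rate_hz rate used when `dg_spike_times` is `NULL`.
#' @param dg_channel channel id carrying the DG trigger spikes.
#' @param wave_onset_lag_ms lag from DG spike to recruitment of the first
#'   wave channel.
#' @param wave_speed_ch_per_ms recruitment speed (channels per ms).
#' @param wave_extent number of channels recruited (0..64; 0 disables).
#' @param wave_amp_sd plateau amplitude in units of the noise SD.
#' @param wave_hold_ms how long each recruited channel stays active.
#' @param wave_origin `c(row, col)` of the first recruited channel.
#' @param spike_amp_sd spike waveform amplitude in noise SDs.
#' @param noise_rms noise RMS (uV).
#' @param duration_s,rate_hz recording length and sampling rate.
#' @param seed RNG seed.
#' @return a `mea_sim_params` list.
#' @export
mea_sim_params <- function(baseline_rate_hz = 0.5, burst_rate_hz = 0,
                           burst_n_spikes = 15, burst_dur_s = 0.15,
                           dg_spike_times = NULL, dg_spike_rate_hz = 0.5,
                           dg_channel = "r7c2",
                           wave_onset_lag_ms = 5, wave_speed_ch_per_ms = 0.25,
                           wave_extent = 12, wave_amp_sd = 6,
                           wave_hold_ms = 60, wave_origin = c(7, 2),
                           spike_amp_sd = 10, noise_rms = 5,
                           duration_s = 20, rate_hz = 10000, seed = 1L) {
  p <- list(baseline_rate_hz = baseline_rate_hz, burst_rate_hz = burst_rate_hz,
            burst_n_spikes = burst_n_spikes, burst_dur_s = burst_dur_s,
            dg_spike_times = dg_spike_times,
            dg_spike_rate_hz = dg_spike_rate_hz, dg_channel = dg_channel,
            wave_onset_lag_ms = wave_onset_lag_ms,
            wave_speed_ch_per_ms = wave_speed_ch_per_ms,
            wave_extent = as.integer(wave_extent), wave_amp_sd = wave_amp_sd,
            wave_hold_ms = wave_hold_ms, wave_origin = wave_origin,
            spike_amp_sd = spike_amp_sd, noise_rms = noise_rms,
            duration_s = duration_s, rate_hz = rate_hz, seed = as.integer(seed))
  stopifnot(p$wave_extent >= 0, p$wave_extent <= 64,
            p$wave_onset_lag_ms >= 0, p$noise_rms >= 0,
            p$duration_s > 0, p$rate_hz >= 5000)
  class(p) <- "mea_sim_params"
  p
}

#' Standard 8x8 MEA geometry
#'
#' Channel ids `r<row>c<col>`, row-major.
#' @return data frame with `channel_id`, `row`, `col` (64 rows).
#' @export
mea_geometry_8x8 <- function() {
  g <- expand.grid(col = 1:8, row = 1:8)
  data.frame(channel_id = paste0("r", g$row, "c", g$col),
             row = g$row, col = g$col)
}

# Recruitment order from an origin on the 8x8 grid: by Chebyshev ring
# (8-connected distance), ties broken row-major. Returns geometry rows in
# recruitment order.
wave_recruitment_order <- function(geometry, origin) {
  d <- pmax(abs(geometry$row - origin[1]), abs(geometry$col - origin[2]))
  geometry[order(d, geometry$row, geometry$col), , drop = FALSE]
}

#' Simulate an 8x8 MEA recording with known ground truth
#'
#' See [mea_sim_params()] for the generative model. The DG trigger channel
#' carries large biphasic spikes; after each, a plateau deflection
#' (`wave_amp_sd` noise SDs, raised-cosine 5 ms edges) recruits channels
#' ring-wise from `wave_origin`. Gaussian white noise on every channel.
#'
#' @param p a [mea_sim_params()].
#' @return list with `recording` (64-channel [recording()] with geometry)
#'   and `truth`: `dg_spikes` (`t_s`), `wave` (`channel_id`, `rank`,
#'   `act_lag_ms`, `hold_ms`), per-channel background `spikes`
#'   (`channel_id`, `t_s`), `bursts` (`channel_id`, `start_s`, `end_s`,
#'   `n_spikes`), echoed `params`.
#' @export
gen_mea_recording <- function(p) {
  stopifnot(inherits(p, "mea_sim_params"))
  set.seed(p$seed)
  geom <- mea_geometry_8x8()
  n <- round(p$duration_s * p$rate_hz)
  dt <- 1 / p$rate_hz
  x <- matrix(0, nrow = 64, ncol = n)
  rownames(x) <- NULL

  # spike waveform: biphasic, ~1.2 ms
  w_len <- round(0.0012 * p$rate_hz)
  w_t <- seq(0, 1, length.out = w_len)
  spike_wave <- -sin(2 * pi * w_t) * exp(-3 * w_t)

  add_spike <- function(ch_i, t, amp) {
    i0 <- floor(t * p$rate_hz) + 1L
    idx <- i0:min(n, i0 + w_len - 1L)
    x[ch_i, idx] <<- x[ch_i, idx] + amp * spike_wave[seq_along(idx)]
  }

  # DG trigger spikes
  if (!is.null(p$dg_spike_times)) {
    dg_t <- sort(p$dg_spike_times)
  } else {
    n_dg <- stats::rpois(1, p$dg_spike_rate_hz * p$duration_s)
    dg_t <- sort(stats::runif(n_dg, 0.2, max(0.2, p$duration_s - 0.2)))
    if (length(dg_t) > 1) dg_t <- dg_t[c(TRUE, diff(dg_t) > 0.3)]
  }
  dg_i <- match(p$dg_channel, geom$channel_id)
  if (is.na(dg_i)) stop("dg_channel not on the 8x8 grid: ", p$dg_channel)
  for (t in dg_t) add_spike(dg_i, t, p$spike_amp_sd * p$noise_rms)

  # propagation wave
  wave <- data.frame(channel_id = character(0), rank = integer(0),
                     act_lag_ms = numeric(0), hold_ms = numeric(0))
  if (p$wave_extent > 0 && length(dg_t) > 0) {
    ord <- wave_recruitment_order(geom, p$wave_origin)
    ord <- ord[seq_len(p$wave_extent), , drop = FALSE]
    lag_ms <- p$wave_onset_lag_ms +
      (seq_len(p$wave_extent) - 1L) / p$wave_speed_ch_per_ms
    wave <- data.frame(channel_id = ord$channel_id,
                       rank = seq_len(p$wave_extent),
                       act_lag_ms = lag_ms, hold_ms = p$wave_hold_ms)
    edge_s <- 0.005
    env_len <- ceiling((p$wave_hold_ms / 1000 + 2 * edge_s) * p$rate_hz) + 1L
    env <- plateau_envelope((0:(env_len - 1L)) * dt,
                            p$wave_hold_ms / 1000, edge_s)
    amp <- p$wave_amp_sd * p$noise_rms
    for (t in dg_t) {
      for (k in seq_len(p$wave_extent)) {
        ch_i <- match(ord$channel_id[k], geom$channel_id)
        t0 <- t + lag_ms[k] / 1000 - edge_s
        i0 <- floor(t0 * p$rate_hz) + 1L
        if (i0 > n) next
        idx <- max(1L, i0):min(n, i0 + env_len - 1L)
        x[ch_i, idx] <- x[ch_i, idx] + amp * env[idx - i0 + 1L]
      }
    }
  }

  # background spikes and burst episodes
  spikes <- vector("list", 64)
  bursts_l <- list()
  for (ch_i in 1:64) {
    t_bg <- numeric(0)
    if (ch_i == dg_i) {         # trigger channel carries only DG spikes
      spikes[[ch_i]] <- t_bg
      next
    }
    if (p$baseline_rate_hz > 0) {
      n_s <- stats::rpois(1, p$baseline_rate_hz * p$duration_s)
      t_bg <- sort(stats::runif(n_s, 0, p$duration_s - 0.002))
    }
    if (p$burst_rate_hz > 0) {
      n_ep <- stats::rpois(1, p$burst_rate_hz * p$duration_s)
      if (n_ep > 0) {
        starts <- stats::runif(n_ep, 0, max(0, p$duration_s - p$burst_dur_s))
        for (s0 in starts) {
          tb <- sort(s0 + stats::runif(p$burst_n_spikes, 0, p$burst_dur_s))
          t_bg <- sort(c(t_bg, tb))
          bursts_l[[length(bursts_l) + 1L]] <-
            data.frame(channel_id = geom$channel_id[ch_i],
                       start_s = min(tb), end_s = max(tb),
                       n_spikes = p$burst_n_spikes)
        }
      }
    }
    # enforce 2 ms refractory in truth
    if (length(t_bg) > 1) t_bg <- t_bg[c(TRUE, diff(t_bg) > 0.002)]
    for (t in t_bg) add_spike(ch_i, t, p$spike_amp_sd * p$noise_rms)
    spikes[[ch_i]] <- t_bg
  }
  spikes_df <- data.frame(
    channel_id = rep(geom$channel_id, vapply(spikes, length, 1L)),
    t_s = unlist(spikes))
  bursts_df <- if (length(bursts_l)) do.call(rbind, bursts_l) else
    data.frame(channel_id = character(0), start_s = numeric(0),
               end_s = numeric(0), n_spikes = integer(0))

  if (p$noise_rms > 0) {
    x <- x + matrix(stats::rnorm(length(x), 0, p$noise_rms), nrow = 64)
  }

  list(
    recording = recording(x, p$rate_hz, channel_ids = geom$channel_id,
                          geometry = geom, units = "uV"),
    truth = list(dg_spikes = data.frame(t_s = dg_t), wave = wave,
                 spikes = spikes_df, bursts = bursts_df, params = p)
  )
}

#' Parameters for the awake-LFP simulator
#'
#' The signal is a 7 Hz theta carrier plus a gamma carrier whose envelope
#' is modulated by theta phase as `base * (1 + m * cos(theta - phi0))`,
#' plus Hann-windowed ripple bursts (150-200 Hz) placed only inside idle
#' epochs, on a 1/f + white noise floor. The epoch schedule alternates
#' idle / running blocks.
#'
#' @param theta_hz,theta_amp theta carrier frequency (Hz) and amplitude (uV).
#' @param gamma_hz,gamma_amp_base gamma carrier frequency and base envelope.
#' @param modulation_depth m in `[0, 1]`.
#' @param phi0 preferred theta phase of gamma (radians). The default
#'   `pi/8` is the center of the phase bin `[0, pi/4)` under the
#'   standard 8-bin partition of `[-pi, pi)`, so binned profiles peak in
#'   an unambiguous bin (a value on a bin boundary would split its peak
#'   between two bins).
#' @param ripple_rate_hz ripple rate during idle epochs.
#' @param ripple_center_hz range (length 2 in `[150, 200]`) from which each
#'   ripple's carrier frequency is drawn uniformly.
#' @param ripple_dur_ms range (length 2) of ripple durations (Hann support).
#' @param ripple_amp ripple peak amplitude (uV).
#' @param idle_block_s,running_block_s alternating schedule block lengths
#'   (schedule starts idle).
#' @param noise_sd total noise SD (uV); `pink_frac` of its variance is 1/f.
#' @param pink_frac fraction of noise variance from the 1/f component.
#' @param n_channels number of identical-statistics channels.
#' @param duration_s,rate_hz length and sampling rate.
#' @param seed RNG seed.
#' @return an `lfp_sim_params` list.
#' @export
lfp_sim_params <- function(theta_hz = 7, theta_amp = 50,
                           gamma_hz = 55, gamma_amp_base = 10,
                           modulation_depth = 0.5, phi0 = pi / 8,
                           ripple_rate_hz = 0.3,
                           ripple_center_hz = c(150, 200),
                           ripple_dur_ms = c(40, 140), ripple_amp = 40,
                           idle_block_s = 12, running_block_s = 12,
                           noise_sd = 10, pink_frac = 0.5,
                           n_channels = 1, duration_s = 60,
                           rate_hz = 1000, seed = 1L) {
  p <- list(theta_hz = theta_hz, theta_amp = theta_amp, gamma_hz = gamma_hz,
            gamma_amp_base = gamma_amp_base,
            modulation_depth = modulation_depth, phi0 = phi0,
            ripple_rate_hz = ripple_rate_hz,
            ripple_center_hz = ripple_center_hz,
            ripple_dur_ms = ripple_dur_ms, ripple_amp = ripple_amp,
            idle_block_s = idle_block_s, running_block_s = running_block_s,
            noise_sd = noise_sd, pink_frac = pink_frac,
            n_channels = as.integer(n_channels), duration_s = duration_s,
            rate_hz = rate_hz, seed = as.integer(seed))
  stopifnot(p$modulation_depth >= 0, p$modulation_depth <= 1,
            p$ripple_center_hz[1] >= 150, p$ripple_center_hz[2] <= 200,
            p$pink_frac >= 0, p$pink_frac <= 1, p$n_channels >= 1)
  class(p) <- "lfp_sim_params"
  p
}

# 1/f-amplitude noise of length n, unit SD, via FFT shaping.
pink_noise <- function(n, rate_hz) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- c(0, seq_len(n - 1)) / n * rate_hz
  f <- pmin(f, rate_hz - f)          # fold to two-sided
  h <- 1 / sqrt(pmax(f, 1))          # flatten below 1 Hz
  h[1] <- 0                          # drop DC
  x <- Re(stats::fft(W * h, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Simulate an awake-LFP recording with known ground truth
#'
#' See [lfp_sim_params()]. Theta phase is defined by the cosine carrier:
#' `theta(t) = 2*pi*theta_hz*t` and the signal contains
#' `theta_amp*cos(theta)`; the Morlet phase estimate at `theta_hz`
#' recovers exactly this angle. Ripples never straddle idle-epoch borders.
#'
#' @param p an [lfp_sim_params()].
#' @return list with `recording`, `epochs` (idle/running table) and
#'   `truth`: `ripples` (`t_mid_s`, `start_s`, `end_s`, `duration_ms`,
#'   `center_hz`), `phi0`, `modulation_depth`, echoed `params`.
#' @export
gen_lfp <- function(p) {
  stopifnot(inherits(p, "lfp_sim_params"))
  set.seed(p$seed)
  n <- round(p$duration_s * p$rate_hz)
  t <- (0:(n - 1)) / p$rate_hz
  theta_phase <- 2 * pi * p$theta_hz * t

  # epoch schedule
  ep <- list()
  pos <- 0
  state <- "idle"
  while (pos < p$duration_s - 1e-9) {
    len <- if (state == "idle") p$idle_block_s else p$running_block_s
    if (len > 0) {
      e <- min(pos + len, p$duration_s)
      ep[[length(ep) + 1L]] <- data.frame(start_s = pos, end_s = e,
                                          state = state)
      pos <- e
    }
    state <- if (state == "running") "idle" else "running"
    if (p$idle_block_s <= 0 && p$running_block_s <= 0) break
  }
  epochs <- do.call(rbind, ep)

  base <- p$theta_amp * cos(theta_phase) +
    p$gamma_amp_base * (1 + p$modulation_depth * cos(theta_phase - p$phi0)) *
      cos(2 * pi * p$gamma_hz * t)

  # ripples inside idle epochs only
  ripples <- data.frame(t_mid_s = numeric(0), start_s = numeric(0),
                        end_s = numeric(0), duration_ms = numeric(0),
                        center_hz = numeric(0))
  ripple_sig <- numeric(n)
  idle_rows <- epochs[epochs$state == "idle", , drop = FALSE]
  if (p$ripple_rate_hz > 0 && nrow(idle_rows) > 0) {
    max_dur_s <- max(p$ripple_dur_ms) / 1000
    for (i in seq_len(nrow(idle_rows))) {
      e0 <- idle_rows$start_s[i]; e1 <- idle_rows$end_s[i]
      avail <- e1 - e0 - max_dur_s - 0.1
      if (avail <= 0) next
      n_r <- stats::rpois(1, p$ripple_rate_hz * (e1 - e0))
      if (n_r == 0) next
      mids <- sort(stats::runif(n_r, e0 + 0.05 + max_dur_s / 2,
                                e1 - 0.05 - max_dur_s / 2))
      # enforce separation so truth events never overlap
      if (length(mids) > 1) mids <- mids[c(TRUE, diff(mids) > max_dur_s + 0.1)]
      for (m in mids) {
        dur_ms <- stats::runif(1, p$ripple_dur_ms[1], p$ripple_dur_ms[2])
        fc <- stats::runif(1, p$ripple_center_hz[1], p$ripple_center_hz[2])
        dur_s <- dur_ms / 1000
        i0 <- floor((m - dur_s / 2) * p$rate_hz) + 1L
        len <- round(dur_s * p$rate_hz)
        idx <- i0:min(n, i0 + len - 1L)
        tt <- (idx - i0) / p$rate_hz
        hann <- 0.5 * (1 - cos(2 * pi * tt / dur_s))
        ripple_sig[idx] <- ripple_sig[idx] +
          p$ripple_amp * hann * sin(2 * pi * fc * tt)
        ripples <- rbind(ripples, data.frame(
          t_mid_s = m, start_s = (i0 - 1L) / p$rate_hz,
          end_s = (i0 - 1L + len) / p$rate_hz,
          duration_ms = dur_ms, center_hz = fc))
      }
    }
  }

  samples <- matrix(0, nrow = p$n_channels, ncol = n)
  for (ch in seq_len(p$n_channels)) {
    noise <- p$noise_sd * (sqrt(p$pink_frac) * pink_noise(n, p$rate_hz) +
                           sqrt(1 - p$pink_frac) * stats::rnorm(n))
    samples[ch, ] <- base + ripple_sig + noise
  }

  list(
    recording = recording(samples, p$rate_hz,
                          channel_ids = paste0("ca1_", seq_len(p$n_channels)),
                          units = "uV"),
    epochs = epochs,
    truth = list(ripples = ripples, phi0 = p$phi0,
                 modulation_depth = p$modulation_depth, params = p)
  )
}
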