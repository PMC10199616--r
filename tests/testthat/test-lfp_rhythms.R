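test_that("LFP preprocessing filters and demeans", {
  rate <- 1500
  t <- (0:(4 * rate - 1)) / rate
  x <- rbind(5 + sin(2 * pi * 100 * t),      # DC + passband tone
             sin(2 * pi * 500 * t))          # stopband tone
  rec <- preprocess_lfp(recording(x, rate))
  expect_lt(max(abs(rowMeans(rec$samples))), 1e-9)
  # 100 Hz passed within 1 dB, 500 Hz attenuated >= 20 dB (steady state)
  core <- (rate):(3 * rate)
  a100 <- sqrt(mean(rec$samples[1, core]^2)) / sqrt(0.5)
  a500 <- sqrt(mean(rec$samples[2, core]^2)) / sqrt(0.5)
  expect_gt(a100, 10^(-1 / 20))
  expect_lt(a500, 10^(-20 / 20))
  # DC-only input maps to zero
  z <- preprocess_lfp(recording(matrix(3, 1, 4 * rate), rate))
  expect_lt(max(abs(z$samples)), 1e-9)
})

test_that("epoch tiling never straddles states and drops remainders", {
  rec <- recording(matrix(0, 1, 20 * 1000), 1000)
  ep <- data.frame(start_s = c(0, 10, 16.5),
                   end_s = c(10, 12.9, 19.9),
                   state = c("idle", "running", "idle"))
  segs <- epoch_signal(rec, ep, len_s = 3)
  expect_equal(length(segs), 3 + 0 + 1)
  expect_equal(vapply(segs, `[[`, "", "state"),
               c("idle", "idle", "idle", "idle"))
  expect_true(all(vapply(segs, function(s) ncol(s$samples), 0L) == 3000))
})

test_that("Morlet band power: tones, linearity, bandwidth scaling", {
  rate <- 1000
  t <- (0:(3 * rate - 1)) / rate
  x7 <- sin(2 * pi * 7 * t)
  p_theta <- morlet_band_power(x7, rate, band = c(3, 12))
  p_gamma <- morlet_band_power(x7, rate, band = c(20, 90))
  expect_gt(p_theta / p_gamma, 100)
  # amplitude scaling: power scales with the square
  expect_equal(morlet_band_power(3 * x7, rate, band = c(3, 12)) / p_theta,
               9, tolerance = 1e-6)
  # white noise: band power proportional to bandwidth
  set.seed(21)
  pw <- replicate(20, {
    xn <- rnorm(3 * rate)
    c(morlet_band_power(xn, rate, band = c(30, 40)),
      morlet_band_power(xn, rate, band = c(30, 60)))
  })
  ratio <- mean(pw[2, ]) / mean(pw[1, ])
  expect_gt(ratio, 2.4)
  expect_lt(ratio, 3.6)
  expect_error(morlet_band_power(x7[1:100], rate, band = c(0.1, 12)),
               "resolution")
})

test_that("band power table covers every segment and band", {
  rec <- recording(matrix(rnorm(2 * 6 * 1000), 2), 1000)
  ep <- data.frame(start_s = c(0, 3), end_s = c(3, 6),
                   state = c("idle", "running"))
  segs <- epoch_signal(rec, ep)
  tbl <- band_power_table(segs)
  expect_equal(nrow(tbl), 2 * 4)
  expect_setequal(unique(tbl$band),
                  c("theta", "low_theta", "high_theta", "gamma"))
  expect_true(all(tbl$power >= 0))
})

test_that("phase-gamma profile peaks at the set coupling phase", {
  p <- lfp_sim_params(modulation_depth = 1, phi0 = pi / 8, seed = 31,
                      duration_s = 30, idle_block_s = 3,
                      running_block_s = 27, ripple_rate_hz = 0)
  sim <- gen_lfp(p)
  segs <- Filter(function(s) s$state == "running",
                 epoch_signal(preprocess_lfp(sim$recording), sim$epochs))
  prof <- phase_gamma_profile(segs)
  expect_equal(nrow(prof), 8L)
  expect_equal(sum(prof$n_samples > 0), 8L)
  # bins partition the circle: widths equal, centers ordered
  expect_equal(diff(prof$bin_center_rad), rep(pi / 4, 7))
  # phi0 = pi/8 lies in bin 5 ([0, pi/4))
  expect_equal(which.max(prof$mean_gamma_power), 5L)
  # constant envelope: bins agree within sampling error
  p0 <- lfp_sim_params(modulation_depth = 0, seed = 32, duration_s = 30,
                       idle_block_s = 3, running_block_s = 27,
                       ripple_rate_hz = 0)
  sim0 <- gen_lfp(p0)
  segs0 <- Filter(function(s) s$state == "running",
                  epoch_signal(preprocess_lfp(sim0$recording), sim0$epochs))
  prof0 <- phase_gamma_profile(segs0)
  expect_lt(diff(range(prof0$mean_gamma_power)) /
              mean(prof0$mean_gamma_power), 0.3)
})

test_that("phase argmax shifts with the coupling phase (equivariance)", {
  for (shift_bins in c(1, 3)) {
    p <- lfp_sim_params(modulation_depth = 1,
                        phi0 = pi / 8 + shift_bins * pi / 4, seed = 33,
                        duration_s = 30, idle_block_s = 3,
                        running_block_s = 27, ripple_rate_hz = 0)
    sim <- gen_lfp(p)
    segs <- Filter(function(s) s$state == "running",
                   epoch_signal(preprocess_lfp(sim$recording), sim$epochs))
    prof <- phase_gamma_profile(segs)
    expect_equal(which.max(prof$mean_gamma_power), 5L + shift_bins)
  }
})

test_that("quadratic fit comparison: identity, oracle F and discrimination", {
  centers <- -pi + (1:8 - 0.5) * pi / 4
  prof <- data.frame(bin_center_rad = rep(centers, 3),
                     mean_gamma_power = rep(10 + centers^2, 3) +
                       rnorm(24, 0, 0.5))
  idres <- compare_quadratic_fits(prof, prof)
  expect_equal(idres$F, 0, tolerance = 1e-9)
  expect_equal(idres$p, 1)

  # closed-form oracle on a 6-point worked dataset via normal equations
  th <- c(-2, -1, 0, 1, 2, 3)
  ya <- c(4.1, 1.2, 0.3, 1.1, 3.9, 9.2)
  yb <- c(8.0, 2.1, 0.2, 2.2, 8.4, 18.1)
  pa <- data.frame(bin_center_rad = th, mean_gamma_power = ya)
  pb <- data.frame(bin_center_rad = th, mean_gamma_power = yb)
  X <- cbind(1, th, th^2)
  sse <- function(y) {
    beta <- solve(t(X) %*% X, t(X) %*% y)
    sum((y - X %*% beta)^2)
  }
  Xp <- rbind(X, X)
  yp <- c(ya, yb)
  beta_p <- solve(t(Xp) %*% Xp, t(Xp) %*% yp)
  ss_shared <- sum((yp - Xp %*% beta_p)^2)
  ss_sep <- sse(ya) + sse(yb)
  Fo <- ((ss_shared - ss_sep) / 3) / (ss_sep / 6)
  res <- compare_quadratic_fits(pa, pb, normalize = FALSE)
  expect_equal(res$F, Fo, tolerance = 1e-10)
  expect_equal(res$df_separate, 6)
  expect_lte(res$ss_separate, res$ss_shared)
  expect_error(compare_quadratic_fits(pa[1:3, ], pb[1:3, ]), "4 distinct")
})

test_that("CFC comparison discriminates coupled from uncoupled signals", {
  # reduced-seed version of the calibration study (full run in acceptance)
  sub_prof <- function(m, seed) {
    p <- lfp_sim_params(modulation_depth = m, seed = seed, duration_s = 33,
                        idle_block_s = 3, running_block_s = 30,
                        ripple_rate_hz = 0)
    sim <- gen_lfp(p)
    segs <- Filter(function(s) s$state == "running",
                   epoch_signal(preprocess_lfp(sim$recording), sim$epochs))
    phase_gamma_replicates(segs)
  }
  hits <- 0
  for (s in 1:5) {
    pa <- sub_prof(0.8, 500 + s)
    pb <- sub_prof(0, 600 + s)
    if (compare_quadratic_fits(pa, pb)$p < 0.05) hits <- hits + 1
  }
  expect_equal(hits, 5L)
})

test_that("ripple detection: zero signal, injected events, invariances", {
  rate <- 1500
  ep <- data.frame(start_s = 0, end_s = 40, state = "idle")
  expect_equal(nrow(detect_ripples_kay(
    recording(matrix(0, 1, 40 * rate), rate), ep)), 0L)

  p <- lfp_sim_params(seed = 41, duration_s = 40, idle_block_s = 40,
                      running_block_s = 0, ripple_rate_hz = 0.4,
                      rate_hz = rate)
  sim <- gen_lfp(p)
  rec <- preprocess_lfp(sim$recording)
  ev <- detect_ripples_kay(rec, sim$epochs)
  tru <- sim$truth$ripples
  hits <- vapply(tru$t_mid_s, function(t) {
    any(ev$start_s < t & ev$end_s > t)
  }, TRUE)
  expect_true(all(hits))
  # all events confined to idle epochs and non-overlapping
  expect_true(all(ev$start_s >= 0 & ev$end_s <= 40))
  if (nrow(ev) > 1) expect_true(all(diff(ev$start_s) > 0) &&
                                all(ev$start_s[-1] >= ev$end_s[-nrow(ev)]))
  # gain invariance: scaling all channels leaves detections unchanged
  rec2 <- rec
  rec2$samples <- rec2$samples * 3.7
  ev2 <- detect_ripples_kay(rec2, sim$epochs, duration_method = "boundary")
  ev1 <- detect_ripples_kay(rec, sim$epochs, duration_method = "boundary")
  expect_equal(ev1, ev2, tolerance = 1e-8)
  # monotone in threshold
  n_hi <- nrow(detect_ripples_kay(rec, sim$epochs, z_thresh = 4,
                                  duration_method = "boundary"))
  expect_lte(n_hi, nrow(ev1))
  expect_error(detect_ripples_kay(rec, data.frame(start_s = 0, end_s = 1,
                                                  state = "running")),
               "idle")
})

test_that("ripple statistics: rates, durations, percentages", {
  ep <- data.frame(start_s = c(0, 700), end_s = c(600, 750),
                   state = c("idle", "running"))
  ev <- data.frame(start_s = seq_len(30), end_s = seq_len(30) + 0.05,
                   duration_ms = rep(c(80, 120), 15), peak_z = 3)
  st <- ripple_stats(ev, ep)
  expect_equal(st$rate_hz, 0.05)
  expect_equal(st$mean_duration_ms, 100)
  expect_equal(st$pct_over_100ms, 50)
  st0 <- ripple_stats(ev[0, ], ep)
  expect_equal(st0$rate_hz, 0)
  expect_true(is.na(st0$mean_duration_ms))
})
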