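test_that("poisson surprise matches a brute-force tail sum", {
  for (n in c(1, 5, 10, 25, 50)) for (tt in c(0.1, 1)) for (lam in c(0.5, 5)) {
    a <- poisson_surprise(n, tt, lam)
    b <- oracle_poisson_tail_log10(n, tt, lam)
    expect_lt(abs(a - b) / abs(b), 1e-10)
  }
  expect_equal(poisson_surprise(0, 1, 1), 0)
  expect_true(is.infinite(poisson_surprise(3, 1, 0)))
  # monotone in n
  s <- vapply(1:30, poisson_surprise, 0, t = 0.5, lambda = 2)
  expect_true(all(diff(s) > 0))
})

test_that("surprise bursts: scripted burst found, small ones rejected", {
  set.seed(1)
  bg <- sort(runif(300, 0, 600))
  burst <- sort(runif(20, 300, 300.15))
  b <- detect_bursts(sort(c(bg, burst)), 600)
  expect_equal(nrow(b), 1L)
  expect_true(all(burst >= b$start_s & burst <= b$end_s))
  expect_gte(b$n_spikes, 20)
  expect_gte(b$surprise, 10)
  # 8 spikes can never satisfy the n >= 10 rule
  b8 <- detect_bursts(sort(c(bg, sort(runif(8, 300, 300.15)))), 600)
  expect_equal(nrow(b8), 0L)
  # every reported burst satisfies the printed rules exactly
  expect_true(all(b$n_spikes >= 10 & b$end_s - b$start_s >= 0.1))
  expect_equal(nrow(detect_bursts(c(1), 600)), 0L)
})

test_that("spike detection: injected spikes recovered, noise bounded", {
  p <- mea_sim_params(seed = 4, duration_s = 5, dg_spike_times = c(1, 2.5, 4),
                      wave_extent = 0, baseline_rate_hz = 0)
  sim <- gen_mea_recording(p)
  st <- detect_spikes(get_channel(sim$recording, "r7c2"), threshold_k = 6)
  expect_equal(length(st[["r7c2"]]), 3L)
  expect_lt(max(abs(st[["r7c2"]] - c(1, 2.5, 4))), 0.0005 + 0.0013)
  # pure-noise false positives stay below the Gaussian tail bound
  set.seed(5)
  noise <- recording(matrix(rnorm(10 * 10000, 0, 5), 1), 10000)
  fp <- detect_spikes(noise, threshold_k = 4)[[1]]
  n <- 10 * 10000
  expect_lte(length(fp), qbinom(0.999, n, 2 * pnorm(-4)))
  expect_error(detect_spikes(recording(matrix(0, 1, 0), 10000)), "empty")
})

test_that("cluster sizes equal the brute-force flood-fill oracle", {
  # deterministic patterns
  expect_equal(max_cluster_size(matrix(TRUE, 8, 8)), 64L)
  expect_equal(max_cluster_size(matrix(FALSE, 8, 8)), 0L)
  checker <- outer(1:8, 1:8, function(r, c) (r + c) %% 2 == 0)
  expect_equal(max_cluster_size(checker), oracle_max_component(checker))
  # random masks across densities
  set.seed(99)
  for (i in 1:300) {
    m <- matrix(runif(64) < runif(1), 8, 8)
    expect_identical(max_cluster_size(m), oracle_max_component(m))
  }
})

test_that("preprocessing decimates to 5 kHz and removes slow drift", {
  geom <- mea_geometry_8x8()
  n <- 4 * 10000
  t <- (0:(n - 1)) / 10000
  drift <- 20 * t                        # slow linear drift
  x <- matrix(rep(drift, each = 64), nrow = 64)
  # add one fast transient on channel 1
  i0 <- 2 * 10000
  x[1, i0:(i0 + 49)] <- x[1, i0:(i0 + 49)] + 30
  rec <- recording(x, 10000, channel_ids = geom$channel_id, geometry = geom)
  out <- preprocess_for_clusters(rec)
  expect_equal(out$rate_hz, 5000)
  expect_equal(ncol(out$samples), n / 2)
  # drift suppressed
  expect_lt(max(abs(out$samples[2, ])), 0.05 * max(drift))
  # transient preserved
  expect_gt(max(out$samples[1, ]), 0.9 * 30 * 0.8)
  # constant signal maps to zero
  cst <- preprocess_for_clusters(
    recording(matrix(5, 64, 2 * 10000), 10000,
              channel_ids = geom$channel_id, geometry = geom))
  expect_lt(max(abs(cst$samples)), 1e-9)
})

test_that("activity clusters at a time point respect thresholds", {
  geom <- mea_geometry_8x8()
  x <- matrix(rnorm(64 * 5000, 0, 1), nrow = 64)
  rec5k <- recording(x, 5000, channel_ids = geom$channel_id, geometry = geom)
  sds <- rep(1, 64)
  # push a 3-channel L-shape strongly positive at t = 0.5
  i <- round(0.5 * 5000) + 1
  ids <- c("r1c1", "r1c2", "r2c2")
  x[match(ids, geom$channel_id), i] <- 10
  rec5k$samples <- x
  cl <- activity_clusters_at(rec5k, 0.5, sds = sds)
  expect_gte(cl$max_pos, 3L)
  expect_error(activity_clusters_at(rec5k, 99), "outside")
})

test_that("cluster timecourse recovers the wave and normalizes exactly", {
  sim <- gen_mea_recording(mea_sim_params(seed = 21, duration_s = 15))
  dg <- detect_spikes(get_channel(sim$recording, "r7c2"),
                      threshold_k = 6)[["r7c2"]]
  rec5k <- preprocess_for_clusters(sim$recording)
  tc <- cluster_timecourse(rec5k, dg)
  expect_equal(tc$mean_curve$lag_ms, seq(0, 100, by = 5))
  raw50 <- tc$mean_curve$raw[tc$mean_curve$lag_ms == 50]
  expect_lt(abs(raw50 - 12), 2 + 1e-9)
  expect_equal(mean(tc$mean_curve$normalized[tc$mean_curve$lag_ms <= 15]), 1)
  # time-shift equivariance: shifting triggers and samples together
  shift_s <- 0.4
  k <- round(shift_s * 5000)
  rec_sh <- recording(cbind(matrix(0, 64, k),
                            rec5k$samples[, 1:(ncol(rec5k$samples) - k)]),
                      5000, channel_ids = rec5k$channel_ids,
                      geometry = rec5k$geometry)
  tc_sh <- cluster_timecourse(rec_sh, dg + shift_s)
  keep <- dg + shift_s + 0.1 < ncol(rec5k$samples) / 5000
  expect_equal(tc_sh$summary$n_triggers, sum(dg + shift_s + 0.1 <= duration_s(rec_sh)))
  # curves for shared triggers agree closely (per-channel SDs shift a little)
  shared <- intersect(round(tc$per_trigger$trigger_t, 6),
                      round(tc_sh$per_trigger$trigger_t - shift_s, 6))
  expect_gt(length(shared), 0)
})

test_that("normalized curve of a constant raw curve is identically 1", {
  geom <- mea_geometry_8x8()
  set.seed(3)
  x <- matrix(rnorm(64 * 10000, 0, 1), nrow = 64)
  rec5k <- recording(x, 5000, channel_ids = geom$channel_id, geometry = geom)
  tc <- cluster_timecourse(rec5k, c(0.5, 1.0))
  # pure noise: raw curve roughly constant, normalized averages to 1 on
  # the first 4 bins by construction
  expect_equal(mean(tc$mean_curve$normalized[tc$mean_curve$lag_ms <= 15]), 1)
})
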