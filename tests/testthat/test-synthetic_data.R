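# Generator properties: spectral slope, RMS calibration, event placement,
# reversal geometry, coupling lag, spike statistics, determinism.

test_that("background noise matches the configured spectrum and RMS", {
  cfg0 <- generator_config(duration = 120, fs = 1000, background_exponent = 0,
                           background_rms = 20, seed = 11)
  set.seed(11)
  white <- generate_background(cfg0, 1)
  ps <- welch_psd(white$samples[1, ], 1000, segment_length = 1)
  sel <- ps$freqs >= 2 & ps$freqs <= 200
  fit <- stats::lm(log10(ps$power[sel]) ~ log10(ps$freqs[sel]))
  expect_lt(abs(stats::coef(fit)[2]), 0.1)

  cfg1 <- generator_config(duration = 120, fs = 1000, background_exponent = 1,
                           background_rms = 20, seed = 12)
  set.seed(12)
  pink <- generate_background(cfg1, 1)
  expect_rel_equal(sqrt(mean(pink$samples[1, ]^2)), 20, 0.05)
  ps1 <- welch_psd(pink$samples[1, ], 1000, segment_length = 1)
  sel <- ps1$freqs >= 2 & ps1$freqs <= 200
  fit1 <- stats::lm(log10(ps1$power[sel]) ~ log10(ps1$freqs[sel]))
  expect_lt(abs(stats::coef(fit1)[2] - (-1)), 0.15)
})

test_that("theta bursts land at the configured rate, duration, amplitude", {
  cfg <- generator_config(duration = 3600, fs = 250, burst_rate = 8.1,
                          burst_duration_mean = 3.5, burst_duration_sd = 0.1,
                          ripple_freq = 100, seed = 21)
  set.seed(21)
  bg <- generate_background(cfg, 1)
  out <- inject_theta_bursts(bg, cfg)
  n <- nrow(out$truth)
  lambda <- 8.1 * 60
  expect_gt(n, stats::qpois(0.025, lambda))
  expect_lt(n, stats::qpois(0.975, lambda))
  expect_lt(abs(mean(out$truth$duration) - 3.5), 0.05)
  # amplitude 0 leaves the background untouched
  set.seed(22)
  bg2 <- generate_background(cfg, 1)
  out2 <- inject_theta_bursts(bg2, cfg, amplitude = 0)
  expect_identical(out2$recording$samples, bg2$samples)
})

test_that("sharp waves reverse across the pyramidal layer", {
  cfg <- generator_config(duration = 600, fs = 1000, spw_rate = 8.6,
                          spw_amplitude = 300, background_rms = 0.1,
                          burst_rate = 0, seed = 31)
  set.seed(31)
  bg <- generate_background(cfg, 3)
  out <- inject_spw_ripples(bg, cfg)
  rec <- out$recording
  idx <- round(out$truth$peak_time * 1000)
  d <- rec$samples[1, idx] - rec$samples[3, idx]   # above - below
  expect_rel_equal(mean(abs(d)), 300, 0.05)
  # opposite polarity above vs below
  expect_true(all(sign(rec$samples[1, idx]) != sign(rec$samples[3, idx])))
  # ripple power at SPW times peaks near the configured ripple frequency
  sg <- morlet_spectrogram(rec$samples[2, (idx[1] - 250):(idx[1] + 250)],
                           1000, freqs = seq(80, 240, by = 10))
  prof <- rowMeans(sg$power[, 200:300])
  expect_true(sg$freqs[which.max(prof)] >= 120 &&
              sg$freqs[which.max(prof)] <= 180)
})

test_that("couple_regions adds a lagged theta drive in one direction", {
  cfg <- generator_config(duration = 120, fs = 1000, burst_rate = 8,
                          coupling_gain = 0.5, coupling_lag = 0.015,
                          seed = 41)
  set.seed(41)
  src <- inject_theta_bursts(generate_background(cfg, 1), cfg)$recording
  dst <- generate_background(cfg, 1, region = "PL")
  expect_identical(couple_regions(src, dst, cfg, gain = 0)$samples,
                   dst$samples)
  coupled <- couple_regions(src, dst, cfg)
  cc <- band_crosscorrelation(src$samples[1, ], coupled$samples[1, ], 1000,
                              band_definition("theta", 4, 12), max_lag = 0.1)
  expect_lt(abs(cc$peak_lag - 0.015), 0.002)
  expect_error(couple_regions(src, dst, cfg, lag = 500), "shorter")
})

test_that("spike trains match configured rates and locking structure", {
  cfg <- generator_config(duration = 900, fs = 1000, n_units = 50,
                          unit_rate = 0.45, locked_fraction = 0, seed = 51)
  set.seed(51)
  out <- generate_spike_trains(cfg)
  rates <- vapply(out$spikes$spike_times, length, 1L) / 900
  expect_lt(abs(mean(rates) - 0.45), 0.02)
  # deterministic light response: probability 1, fixed short latency
  prot <- pulse_protocol(train_frequency = 8, n_repeats = 5)
  cfgl <- generator_config(duration = 60, n_units = 1,
                           light_response_prob = 1,
                           light_latency_sd = 0, unit_rate = 0,
                           locked_fraction = 0, spw_mod_fraction = 0,
                           light_responsive_fraction = 1, seed = 52)
  set.seed(52)
  outl <- generate_spike_trains(cfgl, protocol = prot)
  eff <- stimulation_efficacy(outl$spikes$spike_times[[1]], prot)
  expect_equal(eff$probability, 1.0)
  expect_equal(eff$median_latency, 0.005, tolerance = 1e-6)
})

test_that("generate_session is deterministic under seed", {
  cfg <- generator_config(duration = 90, fs = 500, seed = 7)
  # short sessions may emit the documented achieved-rate warning
  s1 <- suppressWarnings(generate_session(cfg))
  s2 <- suppressWarnings(generate_session(cfg))
  expect_identical(s1$hp$samples, s2$hp$samples)
  expect_identical(s1$spikes_hp$spike_times, s2$spikes_hp$spike_times)
  expect_identical(s1$truth$bursts_hp, s2$truth$bursts_hp)
  cfgB <- generator_config(duration = 90, fs = 500, seed = 8)
  s3 <- suppressWarnings(generate_session(cfgB))
  expect_false(identical(s1$truth$bursts_hp$start, s3$truth$bursts_hp$start))
  # all container invariants hold for the default config
  expect_s3_class(s1$hp, "recording")
  expect_s3_class(s1$spikes_pl, "spike_train_set")
  expect_true(all(diff(s1$truth$bursts_hp$start) > 0))
})
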