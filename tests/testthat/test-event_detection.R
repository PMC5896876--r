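# Detector behaviour on closed-form signals and ground-truth sessions.

test_that("compute_rms matches the closed form for a steady sine", {
  fs <- 1000
  rec <- make_sine_rec(8, fs = fs, dur = 120, amp = 10)
  cr <- compute_rms(rec, band = band_definition("b", 4, 50), window = 0.5)
  mid <- (10 * fs):(110 * fs)
  expect_lt(max(abs(cr$rms[mid] - 10 / sqrt(2))), 0.4)
  z <- recording(matrix(0, 1, 5000), fs)
  expect_equal(max(compute_rms(z, window = 0.2)$rms), 0)
  # amplitude step at t = 5 s: RMS settles within one window either side
  x <- c(rep(0, 5000), sin(2 * pi * 8 * seq(0, 4.999, by = 1e-3)) * 50)
  stepr <- compute_rms(recording(matrix(x, 1), fs), window = 0.2)
  expect_lt(stepr$rms[round(4.7 * fs)], 0.05 * 50 / sqrt(2))
  expect_gt(stepr$rms[round(5.3 * fs)], 0.8 * 50 / sqrt(2))
  expect_error(compute_rms(z, window = 10), "longer than signal")
})

test_that("fit_threshold separates background and burst modes", {
  set.seed(5)
  # bimodal RMS: background mode near 10, burst mode near 50
  rms <- c(rnorm(20000, 10, 1.5), rnorm(2000, 50, 4))
  rms <- rms[rms > 0]
  for (k in c(2, 3, 5)) {
    thr <- fit_threshold(rms, k = k)
    expect_gt(thr$threshold, 10)
    expect_lt(thr$threshold, 50)
  }
  expect_error(fit_threshold(rep(3, 2000)), "degenerate")
  expect_error(fit_threshold(rnorm(100)), ">= 1000")
})

test_that("detection threshold keeps the false-positive rate low on pure noise", {
  cfg <- generator_config(duration = 600, fs = 500, burst_rate = 0,
                          spw_rate = 0, background_rms = 20, seed = 61)
  set.seed(61)
  bg <- generate_background(cfg, 1)
  ev <- detect_oscillations(bg)
  expect_lt(nrow(ev) / 10, 0.5)   # < 0.5 false events/min
})

test_that("merge and duration rules follow the 200 ms / 1 s conventions", {
  # two bursts separated by 150 ms become one event; an isolated 0.8 s
  # burst is discarded
  fs <- 1000
  dur <- 300
  set.seed(71)
  cfg <- generator_config(duration = dur, fs = fs, burst_rate = 0,
                          spw_rate = 0, background_rms = 10, seed = 71)
  bg <- generate_background(cfg, 1)$samples[1, ]
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  add_burst <- function(x, at, len, amp = 150) {
    idx <- which(t >= at & t < at + len)
    u <- (seq_along(idx) - 1) / length(idx)
    env <- ifelse(u < 0.1, u / 0.1, ifelse(u > 0.9, (1 - u) / 0.1, 1))
    x[idx] <- x[idx] + amp * env * sin(2 * pi * 8 * (t[idx] - at))
    x
  }
  x <- add_burst(bg, 100, 2.0)
  x <- add_burst(x, 102.15, 2.0)    # 150 ms gap -> same event
  x <- add_burst(x, 150, 0.8)       # too short -> dropped
  x <- add_burst(x, 200, 3.0)       # isolated control
  ev <- detect_oscillations(recording(matrix(x, 1), fs))
  expect_equal(nrow(ev), 2)
  expect_true(any(ev$start < 101 & ev$stop > 103.5))   # merged pair
  expect_false(any(ev$start > 149 & ev$stop < 152))    # short one gone
})

test_that("detector recovers injected bursts at SNR >= 3", {
  ses <- small_session(seed = 81, duration = 300,
                       background_rms = 110.6 / 3)
  ev <- detect_oscillations(ses$hp, channel = ses$pyr_channel)
  tr <- ses$truth$bursts_hp
  # recall and precision >= 95% (neighbouring bursts occasionally merge)
  expect_lt(abs(nrow(ev) - nrow(tr)) / nrow(tr), 0.05)
  # every detection overlaps a ground-truth interval by >= 80%
  ov <- vapply(seq_len(nrow(ev)), function(i) {
    o <- pmin(ev$stop[i], tr$stop) - pmax(ev$start[i], tr$start)
    max(o / tr$duration)
  }, numeric(1))
  expect_true(all(ov >= 0.8))
  # events are disjoint, sorted, and > 1 s by construction
  expect_true(all(diff(ev$start) > 0))
  expect_true(all(ev$duration > 1))
  expect_true(all(ev$start[-1] >= ev$stop[-nrow(ev)]))
})

test_that("detect_spws sees reversing transients and nothing without them", {
  fs <- 1000
  # identical signals above and below cancel exactly
  set.seed(91)
  x <- rnorm(fs * 120)
  same <- recording(rbind(x, rnorm(fs * 120), x), fs,
                    channel_depths = c(100, 200, 300))
  expect_equal(nrow(detect_spws(same, 2)), 0)
  # injected reversing transient at 8 SD recovered within 10%
  cfg <- generator_config(duration = 600, fs = fs, burst_rate = 0,
                          background_rms = 20, seed = 92)
  set.seed(92)
  bg <- generate_background(cfg, 3)
  d0 <- stats::sd(bg$samples[1, ] - bg$samples[3, ])
  amp <- 8 * d0
  out <- inject_spw_ripples(bg, cfg, amplitude = amp)
  sp <- detect_spws(out$recording, out$pyr_channel)
  expect_equal(nrow(sp), nrow(out$truth))
  expect_rel_equal(mean(sp$amplitude), amp, 0.1)
  matched <- vapply(out$truth$peak_time, function(pt)
    min(abs(sp$peak_time - pt)), numeric(1))
  expect_lt(max(matched), 0.02)
  expect_error(detect_spws(recording(matrix(rnorm(2000), 2, 1000), fs,
                                     channel_depths = c(0, 100)), 1),
               ">= 3 channels")
})

test_that("white-noise SPW rate matches the Gaussian exceedance expectation", {
  # 5-SD peaks of a band-limited Gaussian difference trace: expected
  # upcrossing rate from Rice's formula nu = f_char * exp(-z^2/2)
  fs <- 1000
  set.seed(101)
  rec <- recording(matrix(rnorm(3 * fs * 600), 3), fs,
                   channel_depths = c(100, 200, 300))
  sp <- detect_spws(rec, 2)
  # Rice bound for the 1-300 Hz band: characteristic frequency < 300 Hz
  upper <- 2 * 300 * exp(-25 / 2) * 600   # two-sided, generous factor
  expect_lte(nrow(sp), max(10, 2 * upper))
  expect_gte(nrow(sp), 0)
})

test_that("select_pyr_channel recovers the reversal channel", {
  ses <- small_session(seed = 111, duration = 300)
  expect_equal(select_pyr_channel(ses$hp), ses$pyr_channel)
  # three channels: middle is the only candidate
  cfg <- generator_config(duration = 120, fs = 500, seed = 112,
                          spw_rate = 10)
  set.seed(112)
  out <- inject_spw_ripples(generate_background(cfg, 3), cfg)
  expect_equal(select_pyr_channel(out$recording), 2)
  # no reversal: single-polarity transients on every channel
  set.seed(113)
  mono <- generate_background(cfg, 3)
  w <- rep(exp(-seq(-0.1, 0.1, by = 1 / 500)^2 / (2 * 0.015^2)), 1)
  for (pk in seq(5, 115, by = 2)) {
    idx <- round(pk * 500) + seq_along(w)
    mono$samples[, idx] <- mono$samples[, idx] +
      matrix(rep(300 * w, 3), 3, byrow = TRUE)
  }
  expect_error(select_pyr_channel(mono), "reversal")
})
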