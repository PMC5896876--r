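# Imaginary coherence, wavelet denoising, VAR/gPDC and cross-correlation.

test_that("imaginary coherence is zero for identical signals and flags lags", {
  fs <- 500
  set.seed(151)
  x <- rnorm(60 * fs)
  self <- imaginary_coherence(x, x, fs)
  expect_lt(max(self$coherence, na.rm = TRUE), 1e-20)
  # quarter-cycle delayed 8 Hz component + independent noise: peak at 8 Hz
  t <- seq(0, 120 - 1 / fs, by = 1 / fs)
  s <- sin(2 * pi * 8 * t)
  lagk <- round(fs / (4 * 8))
  y <- c(rep(0, lagk), s[seq_len(length(s) - lagk)]) + rnorm(length(s))
  xs <- s + rnorm(length(s))
  co <- imaginary_coherence(xs, y, fs)
  i8 <- which.min(abs(co$freqs - 8))
  floor_lvl <- stats::quantile(co$coherence[co$freqs > 20 & co$freqs < 200],
                               0.95, na.rm = TRUE)
  expect_gt(co$coherence[i8], 5 * floor_lvl)
  # independent noise: null level below 0.1
  set.seed(152)
  nn <- imaginary_coherence(rnorm(60 * fs), rnorm(60 * fs), fs)
  expect_lt(max(nn$coherence[-1], na.rm = TRUE), 0.1)
})

test_that("imaginary coherence is scale-invariant and symmetric", {
  fs <- 200
  set.seed(153)
  n <- 30 * fs
  z <- rnorm(n)
  x <- z + rnorm(n); y <- c(0, z[-n]) + rnorm(n)
  a <- imaginary_coherence(x, y, fs)
  b <- imaginary_coherence(17 * x, 0.03 * y, fs)
  expect_equal(a$coherence, b$coherence, tolerance = 1e-9)
  swapped <- imaginary_coherence(y, x, fs)
  expect_equal(a$coherence, swapped$coherence, tolerance = 1e-12)
  expect_true(all(a$coherence >= 0 & a$coherence < 1, na.rm = TRUE))
  expect_error(imaginary_coherence(x, y[-1], fs), "equal length")
})

test_that("wavelet_denoise preserves oscillations and shrinks noise", {
  fs <- 1000
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  s <- sin(2 * pi * 8 * t)
  dn <- wavelet_denoise(s)
  expect_lt(sqrt(mean((dn - s)^2)) / sqrt(mean(s^2)), 0.05)
  set.seed(161)
  nz <- rnorm(4096)
  expect_lt(stats::var(wavelet_denoise(nz)), stats::var(nz))
  # burst + noise: band-power fraction improves
  x <- s * 30 + rnorm(length(s), sd = 10)
  frac <- function(v) {
    ps <- welch_psd(v, fs, 1)
    sum(ps$power[ps$freqs >= 4 & ps$freqs <= 30]) / sum(ps$power)
  }
  expect_gt(frac(wavelet_denoise(x)), frac(x))
  # >= 90% of 4-30 Hz power retained
  pb <- function(v) {
    ps <- welch_psd(v, fs, 1)
    sum(ps$power[ps$freqs >= 4 & ps$freqs <= 30])
  }
  expect_gt(pb(wavelet_denoise(x)) / pb(x), 0.9)
  expect_error(wavelet_denoise(rnorm(32)), ">= 64")
})

test_that("fit_var recovers a known VAR(2) and rejects degenerate input", {
  set.seed(171)
  A1 <- matrix(c(0.5, 0.3, 0, 0.4), 2, 2, byrow = TRUE)
  A2 <- matrix(c(-0.2, 0, 0, -0.1), 2, 2, byrow = TRUE)
  n <- 10000
  X <- matrix(0, 2, n)
  for (tt in 3:n)
    X[, tt] <- A1 %*% X[, tt - 1] + A2 %*% X[, tt - 2] + rnorm(2)
  fit <- fit_var(X, max_order = 8)
  expect_equal(fit$p, 2)
  expect_lt(max(abs(fit$A[, , 1] - A1)), 0.05)
  expect_lt(max(abs(fit$A[, , 2] - A2)), 0.05)
  expect_lt(fit$radius, 1)
  # white noise: small order, coefficients ~ 0
  set.seed(172)
  W <- matrix(rnorm(2 * 5000), 2)
  fw <- fit_var(W, max_order = 6)
  expect_lte(fw$p, 2)
  expect_lt(max(abs(fw$A)), 0.08)
  expect_error(fit_var(matrix(1, 2, 500)), "degenerate")
})

test_that("gpdc satisfies the normalization identity and directionality", {
  set.seed(181)
  A1 <- matrix(c(0.5, 0, 0.35, 0.4), 2, 2, byrow = TRUE)  # x drives y only
  n <- 20000
  X <- matrix(0, 2, n)
  for (tt in 2:n) X[, tt] <- A1 %*% X[, tt - 1] + rnorm(2)
  fit <- fit_var(X, max_order = 5)
  freqs <- seq(1, 90, by = 1)
  g <- gpdc(fit, freqs, fs = 200)
  expect_lt(max(abs(apply(g$pi^2, c(2, 3), sum) - 1)), 1e-10)
  expect_true(all(g$pi[2, 1, ] > g$pi[1, 2, ]))
  # estimated values match the closed form evaluated on the true A
  tfit <- structure(list(A = array(A1, c(2, 2, 1)), Sigma = diag(2), p = 1),
                    class = "var_fit")
  gt <- gpdc(tfit, freqs, fs = 200)
  expect_lt(max(abs(g$pi[2, 1, ] - gt$pi[2, 1, ])), 0.05)
  # diagonal VAR: zero cross-terms
  dfit <- structure(list(A = array(diag(c(0.5, 0.4)), c(2, 2, 1)),
                         Sigma = diag(2), p = 1), class = "var_fit")
  gd <- gpdc(dfit, freqs, fs = 200)
  expect_equal(max(abs(gd$pi[2, 1, ])), 0)
  expect_equal(max(abs(gd$pi[1, 2, ])), 0)
})

test_that("directed_coupling_report identifies the injected direction", {
  ses <- generate_session(generator_config(duration = 600, fs = 1000,
                                           n_channels = 3,
                                           coupling_gain = 0.5,
                                           coupling_lag = 0.015,
                                           spw_rate = 0, seed = 191))
  ev <- detect_oscillations(ses$hp, channel = ses$pyr_channel)
  rep <- directed_coupling_report(ses$hp$samples[ses$pyr_channel, ],
                                  ses$pl$samples[1, ], 1000, ev)
  expect_gt(rep$per_band["theta", "x_to_y"], rep$per_band["theta", "y_to_x"])
  expect_gte(rep$n_events, 3)
})

test_that("band_crosscorrelation finds identity and delayed peaks", {
  fs <- 1000
  set.seed(201)
  x <- as.numeric(stats::filter(rnorm(60 * fs), rep(1, 20), sides = 1))
  x[is.na(x)] <- 0
  self <- band_crosscorrelation(x, x, fs)
  expect_equal(self$peak_lag, 0)
  expect_equal(self$peak_value, 1, tolerance = 1e-6)
  k <- round(0.015 * fs)
  y <- c(rep(0, k), x[seq_len(length(x) - k)])
  del <- band_crosscorrelation(x, y, fs)
  expect_lt(abs(del$peak_lag - 0.015), 0.002)
  set.seed(202)
  ind <- band_crosscorrelation(rnorm(60 * fs), rnorm(60 * fs), fs)
  expect_lt(abs(ind$peak_value), 0.1)
})
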