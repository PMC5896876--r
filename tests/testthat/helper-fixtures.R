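# Shared fixtures. Everything is generated in code; sizes are kept small
# (tens of seconds to a few minutes of synthetic signal) so the whole
# suite stays well inside its runtime budget.

# FFT amplitude of the dominant component at frequency f0 (oracle used for
# filter pass/stop-band checks): ratio of the windowed FFT peak magnitude
# near f0 to that of a unit-amplitude reference sine
fft_amplitude <- function(x, fs, f0) {
  n <- length(x)
  X <- Mod(stats::fft(x))[1:(floor(n / 2) + 1)]
  freqs <- (0:floor(n / 2)) * fs / n
  sel <- which(abs(freqs - f0) <= 1)   # +/- 1 Hz search window
  2 * max(X[sel]) / n
}

make_sine_rec <- function(f0, fs = 3200, dur = 60, amp = 1, nch = 1) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  recording(matrix(rep(amp * sin(2 * pi * f0 * t), nch), nrow = nch,
                   byrow = TRUE), fs, region = "test")
}

# small i/vHP-like session for detector tests (fast: low rate, 1 kHz)
small_session <- function(seed = 1, duration = 300, fs = 1000, ...) {
  generate_session(generator_config(duration = duration, fs = fs,
                                    n_channels = 3, seed = seed, ...))
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(abs(object - expected) / abs(expected), tol)
}
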