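# Spectral estimation: Welch PSD on glued segments, event-normalized
# relative power, Morlet spectrograms, band summaries, and event-locked
# (sharp-wave / stimulation) power comparisons.

#' Welch power spectral density over glued segments
#'
#' Splits every supplied segment into non-overlapping windows of
#' `segment_length` seconds, Hann-tapers each, and averages the one-sided
#' periodograms ("gluing" the segments together). Frequency resolution is
#' `1/segment_length`. Windows shorter than `segment_length` are skipped
#' and counted.
#'
#' @param segments Numeric vector or list of numeric vectors (µV).
#' @param fs Sampling rate (Hz).
#' @param segment_length Window length in seconds (1 s for oscillatory
#'   activity, 0.3 s for SPW pre/post, 0.1 s for ripples, 3 s for
#'   light-evoked epochs).
#' @return A `power_spectrum`: freqs (Hz), power (µV²/Hz), segment_length,
#'   n_segments, n_skipped.
#' @export
welch_psd <- function(segments, fs, segment_length = 1) {
  if (!is.list(segments)) segments <- list(segments)
  L <- round(segment_length * fs)
  if (L < 8) stop("segment_length too short for the sampling rate")
  w <- 0.5 * (1 - cos(2 * pi * seq(0, L - 1) / L))   # periodic Hann
  U <- mean(w^2)
  acc <- NULL; n_seg <- 0L; n_skip <- 0L
  for (seg in segments) {
    nw <- floor(length(seg) / L)
    if (nw == 0) { n_skip <- n_skip + 1L; next }
    for (j in seq_len(nw)) {
      x <- seg[((j - 1) * L + 1):(j * L)]
      X <- stats::fft((x - mean(x)) * w)
      p <- Mod(X)^2 / (fs * L * U)
      if (is.null(acc)) acc <- p else acc <- acc + p
      n_seg <- n_seg + 1L
    }
  }
  if (n_seg == 0) stop("no segment reached segment_length; nothing to average")
  p <- acc / n_seg
  half <- floor(L / 2)
  one <- p[1:(half + 1)]
  # one-sided doubling (DC and Nyquist excluded)
  if (L %% 2 == 0) one[2:half] <- 2 * one[2:half]
  else one[2:(half + 1)] <- 2 * one[2:(half + 1)]
  structure(list(freqs = (0:half) * fs / L, power = one,
                 segment_length = segment_length,
                 n_segments = n_seg, n_skipped = n_skip, fs = fs),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum> %d bins, df=%.3g Hz, %d window(s) averaged\n",
              length(x$freqs), 1 / x$segment_length, x$n_segments))
  invisible(x)
}

#' Relative power P(f) / P0(f)
#'
#' Pointwise ratio of two spectra on identical frequency grids (e.g.
#' within-event power normalized to the non-oscillatory baseline). Bins
#' where `P0` is zero are marked `NA` and excluded from band means.
#'
#' @param P,P0 `power_spectrum` objects on the same grid.
#' @return A `relative_power_spectrum` with freqs and ratio.
#' @export
relative_power <- function(P, P0) {
  if (length(P$freqs) != length(P0$freqs) ||
      any(abs(P$freqs - P0$freqs) > 1e-9))
    stop("frequency grids differ")
  ratio <- ifelse(P0$power > 0, P$power / P0$power, NA_real_)
  structure(list(freqs = P$freqs, ratio = ratio), class = "relative_power_spectrum")
}

#' Morlet continuous-wavelet spectrogram
#'
#' Squared modulus of the continuous wavelet transform with a complex
#' Morlet mother wavelet (`n_cycles` cycles, default 6), computed per
#' frequency by FFT convolution. The wavelet is L1-normalized so a unit
#' sinusoid yields a frequency-independent ridge.
#'
#' @param x Numeric signal (µV).
#' @param fs Sampling rate (Hz).
#' @param freqs Analysis frequencies (Hz), within (0, fs/2).
#' @param n_cycles Morlet cycle count (time-frequency trade-off).
#' @param step Time-axis decimation factor (keep every step-th sample).
#' @return A `spectrogram`: times (s), freqs (Hz), power matrix
#'   (freqs x times, µV²).
#' @export
morlet_spectrogram <- function(x, fs, freqs = seq(2, 100, by = 2),
                               n_cycles = 6, step = 1) {
  if (any(freqs <= 0) || any(freqs >= fs / 2))
    stop("freqs must lie in (0, fs/2)")
  n <- length(x)
  X <- stats::fft(x)
  om <- 2 * pi * c(0:(floor(n / 2)), -(ceiling(n / 2) - 1):-1) * fs / n / fs
  # om is angular frequency per sample: 2*pi*f_k/fs
  keep <- seq(1, n, by = step)
  P <- matrix(0, length(freqs), length(keep))
  for (i in seq_along(freqs)) {
    f0 <- 2 * pi * freqs[i] / fs
    sigma <- n_cycles / f0          # wavelet sd in samples
    # L1-normalized analytic Gaussian window around +f0
    H <- exp(-0.5 * sigma^2 * (om - f0)^2)
    W <- stats::fft(X * H, inverse = TRUE) / n   # complex analytic response
    P[i, ] <- Mod(W[keep])^2
  }
  structure(list(times = (keep - 1) / fs, freqs = freqs, power = P),
            class = "spectrogram")
}

#' Mean power inside a frequency band
#'
#' Mean over bins with `f_low <= f < f_high`; `NA` bins (undefined ratios)
#' are excluded.
#'
#' @param spec A `power_spectrum` or `relative_power_spectrum`.
#' @param band A [band_definition()].
#' @export
band_power <- function(spec, band) {
  vals <- if (!is.null(spec$power)) spec$power else spec$ratio
  sel <- spec$freqs >= band$f_low & spec$freqs < band$f_high
  if (!any(sel)) stop("band ", band$name, " contains no frequency bins")
  mean(vals[sel], na.rm = TRUE)
}

#' Within-event vs baseline relative power of a recording
#'
#' Glues 1-s windows from the supplied oscillatory events into P(f), and
#' the complementary (non-oscillatory) stretches into P0(f), returning
#' both and their ratio.
#'
#' @param rec A [recording()].
#' @param events Event data frame from [detect_oscillations()].
#' @param channel Channel analyzed.
#' @param segment_length Welch window (s), default 1.
#' @return List with `P`, `P0`, `relative` and per-band means over
#'   [default_bands()].
#' @export
event_relative_power <- function(rec, events, channel = 1,
                                 segment_length = 1) {
  x <- rec$samples[channel, ]
  fs <- rec$fs
  cut_idx <- function(s, e) x[max(1, round(s * fs)):min(length(x), round(e * fs))]
  ev_segs <- mapply(cut_idx, events$start, events$stop, SIMPLIFY = FALSE)
  bounds <- rbind(c(0, events$stop), c(events$start, rec_duration(rec)))
  base_segs <- lapply(seq_len(ncol(bounds)), function(i)
    if (bounds[2, i] - bounds[1, i] > segment_length)
      cut_idx(bounds[1, i], bounds[2, i]) else numeric(0))
  base_segs <- base_segs[vapply(base_segs, length, 1L) > 0]
  P <- welch_psd(ev_segs, fs, segment_length)
  P0 <- welch_psd(base_segs, fs, segment_length)
  rel <- relative_power(P, P0)
  bands <- default_bands()
  list(P = P, P0 = P0, relative = rel,
       band_means = vapply(bands, function(b) band_power(rel, b), numeric(1)))
}

#' Sharp-wave-triggered power comparison
#'
#' Glues fixed-length windows immediately before and after each SPW peak
#' into pre/post PSDs (0.3-s Welch windows) and computes the SPW-aligned
#' average Morlet spectrogram. Epochs overlapping a neighbouring SPW are
#' dropped and counted.
#'
#' @param rec The downstream [recording()] (e.g. prelimbic).
#' @param spw_times SPW peak times (s).
#' @param pre_window,post_window Seconds gathered before/after each peak.
#' @param channel Channel analyzed.
#' @param segment_length Welch window (s), default 0.3.
#' @param map_halfwidth Spectrogram epoch half-width (s).
#' @param map_freqs Spectrogram frequencies (Hz).
#' @return List with `pre`, `post` (`power_spectrum`), `ratio`
#'   (`relative_power_spectrum` post/pre), `band_means`, `map`
#'   (`spectrogram` averaged across epochs), `n_used`, `n_dropped`.
#' @export
spw_triggered_power <- function(rec, spw_times, pre_window = 0.3,
                                post_window = 0.3, channel = 1,
                                segment_length = 0.3,
                                map_halfwidth = 1,
                                map_freqs = seq(4, 100, by = 2)) {
  if (length(spw_times) < 10) stop("need >= 10 SPWs")
  fs <- rec$fs
  x <- rec$samples[channel, ]
  dur <- rec_duration(rec)
  spw_times <- sort(spw_times)
  gap_prev <- c(Inf, diff(spw_times))
  gap_next <- c(diff(spw_times), Inf)
  usable <- gap_prev > pre_window & gap_next > post_window &
    spw_times - pre_window > 0 & spw_times + post_window < dur
  n_dropped <- sum(!usable)
  tt <- spw_times[usable]
  if (length(tt) < 5) stop("fewer than 5 non-overlapping SPW epochs")
  seg <- function(s, e) x[(round(s * fs) + 1):min(length(x), round(e * fs))]
  pre <- welch_psd(lapply(tt, function(t0) seg(t0 - pre_window, t0)),
                   fs, segment_length)
  post <- welch_psd(lapply(tt, function(t0) seg(t0, t0 + post_window)),
                    fs, segment_length)
  ratio <- relative_power(post, pre)
  # SPW-aligned average time-frequency map
  half <- round(map_halfwidth * fs)
  ok <- tt - map_halfwidth > 0 & tt + map_halfwidth < dur
  acc <- NULL; times <- NULL
  for (t0 in tt[ok]) {
    i0 <- round(t0 * fs)
    sg <- morlet_spectrogram(x[(i0 - half):(i0 + half)], fs, map_freqs,
                             step = max(1, round(fs / 200)))
    acc <- if (is.null(acc)) sg$power else acc + sg$power
    times <- sg$times - map_halfwidth
  }
  map <- structure(list(times = times, freqs = map_freqs,
                        power = acc / sum(ok)), class = "spectrogram")
  bands <- default_bands()
  list(pre = pre, post = post, ratio = ratio,
       band_means = vapply(bands, function(b) band_power(ratio, b), numeric(1)),
       map = map, n_used = length(tt), n_dropped = n_dropped)
}

#' Stimulation-train power modulation
#'
#' For every train: PSD of the stimulation window (train duration) and of
#' the equally long preceding window, both with `segment_length` Welch
#' windows (3 s by default, one window per epoch); ratios are averaged
#' across trains and summarized per band.
#'
#' @param rec The analyzed [recording()].
#' @param protocol A [pulse_protocol()].
#' @param bands List of [band_definition()]s (default theta/beta/gamma).
#' @param channel Channel analyzed.
#' @param segment_length Welch window (s), default 3.
#' @return List with `ratio` (mean P_stim/P_pre spectrum), `band_means`,
#'   `n_trains`, `n_dropped`.
#' @export
stim_power_modulation <- function(rec, protocol, bands = default_bands(),
                                  channel = 1, segment_length = 3) {
  starts <- protocol$train_starts
  if (length(starts) < 5) stop("need >= 5 trains")
  fs <- rec$fs
  x <- rec$samples[channel, ]
  dur <- rec_duration(rec)
  Td <- protocol$train_duration
  ok <- starts - Td > 0 & starts + Td < dur
  n_dropped <- sum(!ok)
  # spectra are averaged across trains before the ratio is taken: the
  # per-train ratio of single-window PSDs is F(2,2)-distributed and has
  # no finite mean, so a ratio-then-average estimator does not converge
  acc_pre <- NULL; acc_stim <- NULL; nfr <- NULL
  for (s in starts[ok]) {
    pre <- welch_psd(x[(round((s - Td) * fs) + 1):round(s * fs)], fs,
                     segment_length)
    stim <- welch_psd(x[(round(s * fs) + 1):round((s + Td) * fs)], fs,
                      segment_length)
    acc_pre <- if (is.null(acc_pre)) pre$power else acc_pre + pre$power
    acc_stim <- if (is.null(acc_stim)) stim$power else acc_stim + stim$power
    nfr <- pre$freqs
  }
  rel <- structure(list(freqs = nfr,
                        ratio = ifelse(acc_pre > 0, acc_stim / acc_pre,
                                       NA_real_)),
                   class = "relative_power_spectrum")
  list(ratio = rel,
       band_means = vapply(bands, function(b) band_power(rel, b), numeric(1)),
       n_trains = sum(ok), n_dropped = n_dropped)
}
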