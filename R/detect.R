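# Detection of discontinuous oscillatory events and sharp waves.
#
# Oscillatory events: the RMS of the 1-100 Hz band-passed signal is
# thresholded at mean + k*SD of a Gaussian fitted to the background mode of
# the RMS histogram (the values between 0 and the histogram's global
# maximum). Supra-threshold cores are extended to the RMS trace's return to
# the fitted background mean, events closer than 200 ms are merged, and
# only events lasting > 1 s are kept.
#
# Sharp waves: peaks of |above - below| (1-300 Hz filtered channels 100 µm
# above/below the pyramidal layer) exceeding 5 SD of the subtracted trace.

#' Sliding-window RMS trace
#'
#' Centered moving-window root mean square of the band-passed first channel
#' (or a chosen channel), same time base as the input; edges are padded by
#' reflection.
#'
#' @param rec A [recording()].
#' @param band Band to filter into before the RMS (default 1-100 Hz).
#' @param window RMS window length in seconds (default 0.2).
#' @param channel Channel index (default 1).
#' @return List with `rms` (µV), `filtered` (the band-passed channel),
#'   `fs`, `window`.
#' @export
compute_rms <- function(rec, band = band_definition("broad", 1, 100),
                        window = 0.2, channel = 1) {
  wlen <- round(window * rec$fs)
  if (wlen < 10) stop("window must span at least 10 samples")
  if (wlen > ncol(rec$samples)) stop("window longer than signal")
  filt <- bandpass_filter(recording(rec$samples[channel, , drop = FALSE],
                                    rec$fs, region = rec$region),
                          band)$samples[1, ]
  rms <- sqrt(moving_average(filt^2, wlen))
  list(rms = rms, filtered = filt, fs = rec$fs, window = window)
}

#' Variance-dependent detection threshold from the RMS histogram
#'
#' Builds a histogram of the RMS values (Freedman-Diaconis bins) restricted
#' to the range from 0 to the bin with the global maximum count, fits a
#' Gaussian to that restricted range by nonlinear least squares, and
#' returns `fitted mean + k * fitted SD`. Falls back to the empirical
#' mean/SD of the restricted values with a warning if the fit fails.
#'
#' @param rms Numeric RMS trace (>= 1000 samples).
#' @param k Threshold multiplier in fitted SDs (default 3).
#' @return List with `threshold`, `mu`, `sigma`, `k`, `method`.
#' @export
fit_threshold <- function(rms, k = 3) {
  if (length(rms) < 1000) stop("need >= 1000 RMS samples to fit a threshold")
  if (stats::sd(rms) == 0 || diff(range(rms)) == 0)
    stop("degenerate RMS histogram (all values equal)")
  bw <- 2 * stats::IQR(rms) / length(rms)^(1 / 3)
  if (bw <= 0) stop("degenerate RMS histogram (zero spread)")
  breaks <- seq(0, max(rms) + bw, by = bw)
  h <- graphics::hist(rms, breaks = breaks, plot = FALSE)
  imax <- which.max(h$counts)
  if (imax < 3) stop("degenerate RMS histogram (mode in the first bins)")
  xs <- h$mids[1:imax]
  ys <- h$counts[1:imax]
  mu0 <- h$mids[imax]
  s0 <- max(bw, stats::sd(rms[rms <= h$breaks[imax + 1]]))
  fit <- tryCatch(
    stats::nls(ys ~ A * exp(-(xs - mu)^2 / (2 * s^2)),
               start = list(A = max(ys), mu = mu0, s = s0),
               control = stats::nls.control(warnOnly = FALSE, maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("Gaussian fit did not converge; using empirical mean + k*SD ",
            "of the sub-mode RMS values")
    vals <- rms[rms <= h$breaks[imax + 1]]
    mu <- mean(vals); s <- stats::sd(vals)
    method <- "empirical"
  } else {
    cf <- stats::coef(fit)
    mu <- unname(cf["mu"]); s <- abs(unname(cf["s"]))
    method <- "gaussian-fit"
  }
  list(threshold = mu + k * s, mu = mu, sigma = s, k = k, method = method)
}

# merge intervals closer than `gap` seconds
merge_close <- function(starts, stops, gap) {
  if (!length(starts)) return(list(starts = starts, stops = stops))
  ms <- starts[1]; me <- stops[1]
  out_s <- c(); out_e <- c()
  for (i in seq_along(starts)[-1]) {
    if (starts[i] - me < gap) me <- max(me, stops[i])
    else { out_s <- c(out_s, ms); out_e <- c(out_e, me)
           ms <- starts[i]; me <- stops[i] }
  }
  list(starts = c(out_s, ms), stops = c(out_e, me))
}

#' Detect discontinuous oscillatory events
#'
#' @param rec A [recording()] of duration >= 60 s.
#' @param band Detection band (default 1-100 Hz).
#' @param amp_band Band on which event amplitude is measured
#'   (default 4-100 Hz).
#' @param window RMS window (s).
#' @param k Threshold multiplier (fitted SDs above the fitted mean).
#' @param merge_gap Events closer than this are considered one (s).
#' @param min_duration Minimum event duration (s), strict (`>`).
#' @param channel Channel analyzed.
#' @return Data frame of events: region, channel, start, stop, duration,
#'   peak_amplitude (µV, cycle-smoothed envelope peak of the `amp_band`
#'   trace), amplitude_raw (max absolute `amp_band` deflection), with the
#'   threshold fit attached as attribute `"threshold"`.
#' @export
detect_oscillations <- function(rec, band = band_definition("broad", 1, 100),
                                amp_band = band_definition("amp", 4, 100),
                                window = 0.2, k = 3, merge_gap = 0.2,
                                min_duration = 1, channel = 1) {
  if (rec_duration(rec) < 60)
    stop("need >= 60 s of signal for threshold estimation")
  cr <- compute_rms(rec, band = band, window = window, channel = channel)
  thr <- fit_threshold(cr$rms, k = k)
  above <- cr$rms > thr$threshold
  fs <- rec$fs
  d <- diff(c(FALSE, above, FALSE))
  core_s <- which(d == 1)
  core_e <- which(d == -1) - 1
  # supra-threshold cores within merge_gap are one oscillation; the > 1 s
  # inclusion rule applies to the merged core span (so brief noise
  # excursions never survive), the reported extent is then the surrounding
  # above-baseline interval
  m <- merge_close((core_s - 1) / fs, core_e / fs, merge_gap)
  keep <- (m$stops - m$starts) > min_duration
  core_starts <- m$starts[keep]; core_stops <- m$stops[keep]
  below_mu <- cr$rms <= thr$mu
  n <- length(cr$rms)
  starts <- numeric(length(core_starts)); stops <- numeric(length(core_starts))
  for (i in seq_along(core_starts)) {
    s <- round(core_starts[i] * fs) + 1
    while (s > 1 && !below_mu[s - 1]) s <- s - 1
    e <- round(core_stops[i] * fs)
    while (e < n && !below_mu[e + 1]) e <- e + 1
    starts[i] <- (s - 1) / fs; stops[i] <- e / fs
  }
  if (length(starts)) {
    m <- merge_close(starts, stops, merge_gap)
    starts <- m$starts; stops <- m$stops
  }
  # peak_amplitude: envelope peak of the dominant theta component
  # (4-12 Hz Hilbert envelope smoothed over two theta cycles), which is
  # near-unbiased for the oscillation's envelope peak under broadband
  # noise; amplitude_raw keeps the max absolute 4-100 Hz deflection
  filt_amp <- bandpass_filter(recording(rec$samples[channel, , drop = FALSE],
                                        rec$fs, region = rec$region),
                              amp_band)$samples[1, ]
  filt_th <- bandpass_filter(recording(rec$samples[channel, , drop = FALSE],
                                       rec$fs, region = rec$region),
                             band_definition("theta", 4, 12))$samples[1, ]
  env_s <- moving_average(Mod(hilbert_analytic(filt_th)),
                          max(3, round(0.25 * fs)))
  peak_amp <- numeric(length(starts)); raw_amp <- numeric(length(starts))
  half_pk <- round(0.5 * fs)
  for (i in seq_along(starts)) {
    idx <- max(1, round(starts[i] * fs)):min(n, round(stops[i] * fs))
    # envelope peak read as the mean over 1 s centred on the envelope
    # argmax: insensitive to single noise bumps, near-unbiased for the
    # envelope's peak region
    imax <- idx[which.max(env_s[idx])]
    win <- intersect(idx, (imax - half_pk):(imax + half_pk))
    peak_amp[i] <- mean(env_s[win])
    raw_amp[i] <- max(abs(filt_amp[idx]))
  }
  ev <- data.frame(region = rep(rec$region, length(starts)),
                   channel = rep(channel, length(starts)),
                   start = starts, stop = stops,
                   duration = stops - starts,
                   peak_amplitude = peak_amp,
                   amplitude_raw = raw_amp)
  stopifnot(all(ev$duration > min_duration),
            !is.unsorted(ev$start),
            all(ev$start[-1] - ev$stop[-nrow(ev)] >= merge_gap | nrow(ev) < 2))
  attr(ev, "threshold") <- thr
  ev
}

#' Detect sharp waves by cross-layer subtraction
#'
#' Filters the channels nearest to 100 µm above and below the pyramidal
#' channel into 1-300 Hz, forms `d(t) = above - below`, and returns peaks
#' with `|d| > 5 SD(d)` separated by a refractory gap.
#'
#' @param rec Hippocampal [recording()] with >= 3 channels.
#' @param pyr_channel Pyramidal-layer channel index.
#' @param n_sd Threshold in SDs of the subtracted trace (default 5).
#' @param refractory Minimum peak separation (s, default 0.1).
#' @param band Filter band (default 1-300 Hz; clipped below Nyquist).
#' @return Data frame of events: region, peak_time, amplitude (|d| at
#'   peak), polarity, pyr_channel; threshold attached as attribute.
#' @export
detect_spws <- function(rec, pyr_channel, n_sd = 5, refractory = 0.1,
                        band = band_definition("spw", 1, 300)) {
  nch <- nrow(rec$samples)
  if (nch < 3) stop("need >= 3 channels for cross-layer subtraction")
  depths <- rec$channel_depths
  target_above <- depths[pyr_channel] - 100
  target_below <- depths[pyr_channel] + 100
  cand <- setdiff(seq_len(nch), pyr_channel)
  above <- cand[which.min(abs(depths[cand] - target_above))]
  below <- cand[which.min(abs(depths[cand] - target_below))]
  if (abs(depths[above] - target_above) > 25 ||
      abs(depths[below] - target_below) > 25)
    warning("no recording sites at exactly +/-100 um; using nearest depths (",
            depths[above], ", ", depths[below], " um)")
  if (band$f_high >= rec$fs / 2)
    band <- band_definition(band$name, band$f_low, 0.45 * rec$fs)
  two <- bandpass_filter(recording(rec$samples[c(above, below), ,
                                               drop = FALSE],
                                   rec$fs,
                                   channel_depths = depths[c(above, below)],
                                   region = rec$region), band)
  d <- two$samples[1, ] - two$samples[2, ]
  thr <- n_sd * stats::sd(d)
  absd <- abs(d)
  over <- which(absd > thr)
  if (!length(over))
    return(structure(data.frame(region = character(0),
                                peak_time = numeric(0),
                                amplitude = numeric(0),
                                polarity = numeric(0),
                                pyr_channel = integer(0)),
                     threshold = thr))
  # local maxima of |d| among supra-threshold samples, then refractory prune
  ispk <- over[absd[over] >= absd[pmax(over - 1, 1)] &
               absd[over] >= absd[pmin(over + 1, length(d))]]
  o <- ispk[order(-absd[ispk])]
  keep <- logical(0); acc <- numeric(0)
  for (i in o) {
    if (!length(acc) || all(abs(i - acc) > refractory * rec$fs))
      acc <- c(acc, i)
  }
  acc <- sort(acc)
  # amplitude: |d| averaged over +/-5 ms around the peak, which removes
  # most of the extreme-value bias a single-sample max would carry
  hw <- max(1, round(0.005 * rec$fs))
  amp <- vapply(acc, function(i)
    mean(absd[max(1, i - hw):min(length(absd), i + hw)]), numeric(1))
  structure(data.frame(region = rep(rec$region, length(acc)),
                       peak_time = (acc - 1) / rec$fs,
                       amplitude = amp,
                       polarity = sign(d[acc]),
                       pyr_channel = rep(pyr_channel, length(acc))),
            threshold = thr)
}

#' Identify the pyramidal-layer channel by polarity reversal
#'
#' Scores every interior channel by the sign flip of the SPW-triggered
#' average on its neighbours: candidate events are collected on each
#' adjacent pair's subtracted trace and the channel whose flanking
#' channels show the most anti-correlated event-triggered averages wins.
#'
#' @param rec Hippocampal [recording()] with >= 3 channels.
#' @param n_sd Detection threshold used during the scan.
#' @return Channel index.
#' @export
select_pyr_channel <- function(rec, n_sd = 5) {
  nch <- nrow(rec$samples)
  if (nch < 3) stop("need >= 3 channels")
  interior <- 2:(nch - 1)
  scores <- rep(NA_real_, nch)
  for (ch in interior) {
    evs <- tryCatch(detect_spws(rec, ch, n_sd = n_sd), error = function(e) NULL)
    if (is.null(evs) || nrow(evs) < 3) next
    lo <- bandpass_filter(recording(rec$samples[c(ch - 1, ch + 1), ,
                                                drop = FALSE], rec$fs,
                                    channel_depths = rec$channel_depths[c(ch - 1, ch + 1)],
                                    region = rec$region),
                          band_definition("spw", 1, min(300, 0.45 * rec$fs)))
    idx <- round(evs$peak_time * rec$fs) + 1
    a <- lo$samples[1, idx]; b <- lo$samples[2, idx]
    # reversal: flanking deflections of opposite sign, large product
    scores[ch] <- -mean(a * b) * nrow(evs)
  }
  if (all(is.na(scores)) || max(scores, na.rm = TRUE) <= 0)
    stop("no polarity reversal found; choose the pyramidal channel manually")
  which.max(scores)
}
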