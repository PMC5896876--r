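# Signal conditioning applied before any analysis stage: zero-phase
# band-limiting, anti-aliased decimation, and the spike-band view.

#' Zero-phase band-pass filter a recording
#'
#' Forward-backward (phase-preserving) Butterworth band-pass of every
#' channel. The default order 3 is applied twice, so the effective roll-off
#' is that of a 6th-order magnitude response.
#'
#' @param rec A [recording()].
#' @param band A [band_definition()].
#' @param order Butterworth prototype order (default 3).
#' @return A band-limited `recording` with identical geometry.
#' @export
bandpass_filter <- function(rec, band, order = 3) {
  nyq <- rec$fs / 2
  if (band$f_high >= nyq)
    stop("invalid band: upper edge ", band$f_high, " Hz >= Nyquist ", nyq, " Hz")
  des <- butter_design(order, c(band$f_low, band$f_high) / nyq, "pass")
  padlen <- ceiling(3 * rec$fs / band$f_low)
  if (ncol(rec$samples) <= 3 * (2 * order + 1))
    stop("insufficient data: signal shorter than filter settling span")
  out <- rec
  for (ch in seq_len(nrow(rec$samples)))
    out$samples[ch, ] <- filtfilt(des$b, des$a, rec$samples[ch, ],
                                  padlen = min(ncol(rec$samples) - 1, padlen))
  out
}

#' Zero-phase low-pass filter a recording
#'
#' @param rec A [recording()].
#' @param f_cut Cut-off frequency (Hz).
#' @param order Butterworth prototype order.
#' @export
lowpass_filter <- function(rec, f_cut, order = 3) {
  nyq <- rec$fs / 2
  if (f_cut >= nyq) stop("invalid cut-off: >= Nyquist")
  des <- butter_design(order, f_cut / nyq, "low")
  out <- rec
  for (ch in seq_len(nrow(rec$samples)))
    out$samples[ch, ] <- filtfilt(des$b, des$a, rec$samples[ch, ],
                                  padlen = min(ncol(rec$samples) - 1,
                                               ceiling(3 * rec$fs / f_cut)))
  out
}

#' Anti-aliased decimation to a lower sampling rate
#'
#' Low-pass filters (zero-phase Butterworth, cut-off at 0.4 of the target
#' rate's Nyquist-doubled value, i.e. `0.4 * target_fs`) and keeps every
#' k-th sample. `fs` must be an integer multiple of `target_fs`.
#'
#' @param rec A [recording()].
#' @param target_fs Target sampling rate (Hz).
#' @export
downsample <- function(rec, target_fs) {
  if (target_fs <= 0) stop("target_fs must be > 0")
  if (target_fs >= rec$fs) {
    warning("target_fs >= fs; returning recording unchanged")
    return(rec)
  }
  k <- rec$fs / target_fs
  if (abs(k - round(k)) > 1e-9)
    stop("fs must be an integer multiple of target_fs (got ratio ", k, ")")
  k <- round(k)
  low <- lowpass_filter(rec, 0.4 * target_fs, order = 3)
  idx <- seq(1, ncol(rec$samples), by = k)
  out <- low
  out$samples <- low$samples[, idx, drop = FALSE]
  out$fs <- target_fs
  out
}

#' Spike-band (multi-unit activity) view of a wide-band recording
#'
#' Band-passes 500-5000 Hz; if the sampling rate cannot support the 5 kHz
#' upper edge, the edge is clipped to `0.45 * fs` with a warning.
#'
#' @param rec A wide-band [recording()] (fs >= 10 kHz recommended).
#' @param order Butterworth prototype order.
#' @export
mua_filter <- function(rec, order = 3) {
  hi <- 5000
  if (0.45 * rec$fs < hi) {
    hi <- 0.45 * rec$fs
    warning("sampling rate too low for a 5 kHz edge; clipped to ", hi, " Hz")
  }
  if (hi <= 500) stop("sampling rate too low for the 500 Hz spike band")
  bandpass_filter(rec, band_definition("mua", 500, hi), order = order)
}
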