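# Domain containers. Plain S3 lists with constructors that validate the
# invariants once, print methods, and small accessors — the style of base-R
# analysis packages (cf. survival, ape) rather than S4.

#' Multi-channel continuous recording
#'
#' Container for a block of simultaneously sampled extracellular channels
#' from one region, in microvolts.
#'
#' @param samples Numeric matrix, channels x samples (µV).
#' @param fs Sampling rate in Hz.
#' @param channel_depths Per-channel depth offsets in µm, strictly monotonic;
#'   larger values are deeper (more ventral).
#' @param region Region label, e.g. "PL", "dHP", "ivHP".
#' @param t0 Recording start time in seconds (timestamps are `t0 + i/fs`).
#' @return An object of class `recording`.
#' @export
recording <- function(samples, fs, channel_depths = NULL, region = "region",
                      t0 = 0) {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1)
  if (!is.matrix(samples) || !is.numeric(samples))
    stop("samples must be a numeric matrix (channels x samples)")
  if (!all(is.finite(samples))) stop("voltage values must be finite")
  if (length(fs) != 1 || fs <= 0) stop("fs must be a positive scalar")
  nch <- nrow(samples)
  if (is.null(channel_depths)) channel_depths <- seq_len(nch) * 100
  if (length(channel_depths) != nch)
    stop("channel_depths length must match channel count")
  d <- diff(channel_depths)
  if (nch > 1 && !(all(d > 0) || all(d < 0)))
    stop("channel_depths must be strictly monotonic")
  structure(list(samples = samples, fs = fs,
                 channel_depths = as.numeric(channel_depths),
                 region = region, t0 = t0),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> region=%s  %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              x$region, nrow(x$samples), ncol(x$samples), x$fs,
              ncol(x$samples) / x$fs))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec A `recording`.
#' @export
rec_duration <- function(rec) ncol(rec$samples) / rec$fs

#' Time axis of a recording
#' @param rec A `recording`.
#' @export
rec_times <- function(rec) rec$t0 + (seq_len(ncol(rec$samples)) - 1) / rec$fs

#' Set of sorted spike trains
#'
#' @param spike_times Named list of numeric vectors, one per unit; strictly
#'   increasing spike times in seconds within `[0, recording_duration]`.
#' @param region Region label.
#' @param recording_duration Duration in seconds the trains live in.
#' @return An object of class `spike_train_set`.
#' @export
spike_train_set <- function(spike_times, region = "region",
                            recording_duration) {
  if (!is.list(spike_times)) stop("spike_times must be a list of numeric vectors")
  if (is.null(names(spike_times)) || any(names(spike_times) == ""))
    names(spike_times) <- sprintf("u%03d", seq_along(spike_times))
  for (id in names(spike_times)) {
    st <- spike_times[[id]]
    if (length(st) && (is.unsorted(st, strictly = TRUE)))
      stop("spike times must be strictly increasing (unit ", id, ")")
    if (length(st) && (st[1] < 0 || st[length(st)] > recording_duration))
      stop("spike times outside [0, recording_duration] (unit ", id, ")")
  }
  structure(list(unit_ids = names(spike_times), spike_times = spike_times,
                 region = region,
                 recording_duration = recording_duration),
            class = "spike_train_set")
}

#' @export
print.spike_train_set <- function(x, ...) {
  n <- vapply(x$spike_times, length, integer(1))
  cat(sprintf("<spike_train_set> region=%s  %d unit(s), %d spikes over %.1f s\n",
              x$region, length(n), sum(n), x$recording_duration))
  invisible(x)
}

#' Frequency band definition
#'
#' @param name Band label ("theta", "beta", ...).
#' @param f_low,f_high Band edges in Hz, `0 < f_low < f_high`.
#' @export
band_definition <- function(name, f_low, f_high) {
  if (!(f_low > 0 && f_high > f_low)) stop("need 0 < f_low < f_high")
  structure(list(name = name, f_low = f_low, f_high = f_high),
            class = "band_definition")
}

#' Canonical analysis bands: theta 4-12, beta 12-30, gamma 30-100 Hz
#' @export
default_bands <- function() list(
  theta = band_definition("theta", 4, 12),
  beta  = band_definition("beta", 12, 30),
  gamma = band_definition("gamma", 30, 100)
)

#' Optogenetic pulse-train protocol
#'
#' Builds the full pulse-onset sequence for a repeated pulse-train protocol:
#' trains of `train_frequency` Hz pulses of `pulse_width` s lasting
#' `train_duration` s, separated by `inter_train_interval` s, repeated
#' `n_repeats` times.
#'
#' @param train_frequency Within-train pulse rate (Hz).
#' @param train_duration Train length (s).
#' @param inter_train_interval Gap between train onsets beyond the train (s).
#' @param n_repeats Number of trains.
#' @param pulse_width Pulse length (s).
#' @param t_start Onset of the first train (s).
#' @export
pulse_protocol <- function(train_frequency = 8, train_duration = 3,
                           inter_train_interval = 6, n_repeats = 30,
                           pulse_width = 0.003, t_start = 0) {
  if (train_frequency <= 0 || train_duration <= 0 || n_repeats < 1)
    stop("invalid protocol parameters")
  per_train <- floor(train_duration * train_frequency)
  starts <- t_start + (seq_len(n_repeats) - 1) *
    (train_duration + inter_train_interval)
  onsets <- as.vector(outer((seq_len(per_train) - 1) / train_frequency,
                            starts, `+`))
  onsets <- sort(onsets)
  stopifnot(!is.unsorted(onsets, strictly = TRUE))
  structure(list(pulse_onsets = onsets, pulse_width = pulse_width,
                 train_frequency = train_frequency,
                 train_duration = train_duration,
                 inter_train_interval = inter_train_interval,
                 n_repeats = n_repeats,
                 train_starts = starts),
            class = "pulse_protocol")
}

#' @export
print.pulse_protocol <- function(x, ...) {
  cat(sprintf("<pulse_protocol> %g Hz x %g s trains, %d repeats, %g ms pulses\n",
              x$train_frequency, x$train_duration, x$n_repeats,
              1000 * x$pulse_width))
  invisible(x)
}
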