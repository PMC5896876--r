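# Unit-level analyses: firing rates, sharp-wave-triggered histograms,
# Hilbert-phase locking with Rayleigh testing, and light-evoked spiking.

#' Mean firing rate
#'
#' @param train Spike times (s).
#' @param duration Observation time (s), > 0.
#' @return Rate in Hz (`count / duration`).
#' @export
firing_rate <- function(train, duration) {
  if (duration <= 0) stop("duration must be positive")
  length(train) / duration
}

#' Event-triggered spike-time histogram (PSTH)
#'
#' Aligns every unit's spikes to every trigger and averages the binned
#' counts into a rate. Overlapping trigger windows are counted
#' independently.
#'
#' @param trains A [spike_train_set()] or list of spike-time vectors.
#' @param triggers Trigger times (s), e.g. SPW peaks (>= 10).
#' @param window Half-width of the window around each trigger (s).
#' @param binsize Bin width (s).
#' @return A `psth`: bin_centers (s, trigger-relative), rate (Hz),
#'   n_triggers, n_units.
#' @export
spw_triggered_psth <- function(trains, triggers, window = 3, binsize = 0.1) {
  if (inherits(trains, "spike_train_set")) trains <- trains$spike_times
  if (length(triggers) < 10) stop("need >= 10 triggers")
  edges <- seq(-window, window, by = binsize)
  centers <- edges[-1] - binsize / 2
  counts <- numeric(length(centers))
  for (st in trains) {
    for (tg in triggers) {
      rel <- st[st >= tg - window & st < tg + window] - tg
      if (length(rel))
        counts <- counts + tabulate(findInterval(rel, edges),
                                    nbins = length(centers))
    }
  }
  rate <- counts / (length(triggers) * length(trains) * binsize)
  structure(list(bin_centers = centers, rate = rate,
                 n_triggers = length(triggers), n_units = length(trains)),
            class = "psth")
}

#' Instantaneous LFP phase at spike times
#'
#' Band-pass filters the LFP, takes the Hilbert-transform analytic phase
#' and samples it at the nearest sample to each spike. Phase convention:
#' 0 rad at the band-filtered LFP peak, phases in (-pi, pi].
#'
#' @param train Spike times (s).
#' @param lfp Numeric LFP vector (µV) or a [recording()] (first channel).
#' @param fs Sampling rate (Hz; taken from the recording if given).
#' @param band A [band_definition()] (default theta 4-12 Hz).
#' @return Numeric phases (rad); spikes outside the LFP range are dropped
#'   with their count in attribute `"n_dropped"`.
#' @export
spike_phases <- function(train, lfp, fs = NULL,
                         band = band_definition("theta", 4, 12)) {
  if (inherits(lfp, "recording")) { fs <- lfp$fs; lfp <- lfp$samples[1, ] }
  if (is.null(fs)) stop("fs required when lfp is a plain vector")
  des <- butter_design(3, c(band$f_low, band$f_high) / (fs / 2), "pass")
  xf <- filtfilt(des$b, des$a, lfp,
                 padlen = min(length(lfp) - 1, ceiling(3 * fs / band$f_low)))
  ph <- Arg(hilbert_analytic(xf))
  idx <- round(train * fs) + 1
  ok <- idx >= 1 & idx <= length(ph)
  out <- ph[idx[ok]]
  attr(out, "n_dropped") <- sum(!ok)
  out
}

#' Rayleigh test for non-uniformity of circular data
#'
#' Resultant length `R = |mean(exp(i phase))|`, `Z = n R^2`, with the
#' small-sample-corrected p-value approximation
#' `p = exp(sqrt(1 + 4n + 4(n^2 - (nR)^2)) - (1 + 2n))`.
#'
#' @param phases Phases in radians.
#' @param min_n Minimum sample size to test (default 10); below it the
#'   result is flagged untested (`p = NA`).
#' @return List with n, mean_phase, R, Z, p.
#' @export
rayleigh_test <- function(phases, min_n = 10) {
  n <- length(phases)
  m <- mean(exp(1i * phases))
  R <- Mod(m)
  Z <- n * R^2
  p <- if (n >= min_n)
    min(1, exp(sqrt(1 + 4 * n + 4 * (n^2 - (n * R)^2)) - (1 + 2 * n)))
  else NA_real_
  list(n = n, mean_phase = Arg(m), R = R, Z = Z, p = p)
}

#' Phase locking of every unit to an LFP band
#'
#' @param trains A [spike_train_set()].
#' @param lfp LFP vector or [recording()] the spikes are tested against.
#' @param fs Sampling rate (if `lfp` is a vector).
#' @param band A [band_definition()].
#' @param events Optional event data frame: only spikes inside these
#'   intervals are used (locking is defined during network oscillations).
#' @param alpha Significance level for the locked flag.
#' @param min_spikes Minimum spikes to test a unit.
#' @return Data frame: unit_id, n_spikes, mean_phase, R, rayleigh_p,
#'   locked, tested.
#' @export
phase_locking <- function(trains, lfp, fs = NULL,
                          band = band_definition("theta", 4, 12),
                          events = NULL, alpha = 0.05, min_spikes = 10) {
  sts <- if (inherits(trains, "spike_train_set")) trains$spike_times else trains
  res <- lapply(names(sts), function(id) {
    st <- sts[[id]]
    if (!is.null(events) && nrow(events)) {
      keep <- rep(FALSE, length(st))
      for (i in seq_len(nrow(events)))
        keep <- keep | (st >= events$start[i] & st <= events$stop[i])
      st <- st[keep]
    }
    ph <- spike_phases(st, lfp, fs = fs, band = band)
    rt <- rayleigh_test(ph, min_n = min_spikes)
    data.frame(unit_id = id, n_spikes = rt$n, mean_phase = rt$mean_phase,
               R = rt$R, rayleigh_p = rt$p,
               locked = !is.na(rt$p) && rt$p < alpha,
               tested = !is.na(rt$p))
  })
  do.call(rbind, res)
}

#' Fraction of significantly locked units
#'
#' @param results Data frame from [phase_locking()].
#' @param alpha Significance level (re-applied to the stored p-values).
#' @return List with n_locked, n_tested, fraction.
#' @export
locked_fraction <- function(results, alpha = 0.05) {
  if (!nrow(results)) stop("empty results")
  tested <- results[results$tested, , drop = FALSE]
  n_locked <- sum(tested$rayleigh_p < alpha)
  list(n_locked = n_locked, n_tested = nrow(tested),
       fraction = if (nrow(tested)) n_locked / nrow(tested) else NA_real_)
}

#' Light-stimulation efficacy of one unit
#'
#' Spikes within the 15-ms window after pulse onset count as light-evoked;
#' efficacy is the probability of at least one evoked spike per pulse.
#'
#' @param train Spike times (s).
#' @param protocol A [pulse_protocol()] (>= 10 pulses).
#' @param window Evoked window after pulse onset (s, default 0.015).
#' @return List with probability, n_pulses, median_latency (s; NA when no
#'   evoked spikes), latencies.
#' @export
stimulation_efficacy <- function(train, protocol, window = 0.015) {
  onsets <- protocol$pulse_onsets
  if (length(onsets) < 10) stop("need >= 10 pulses")
  first_lat <- vapply(onsets, function(o) {
    s <- train[train >= o & train < o + window]
    if (length(s)) s[1] - o else NA_real_
  }, numeric(1))
  hit <- !is.na(first_lat)
  list(probability = mean(hit), n_pulses = length(onsets),
       median_latency = if (any(hit)) stats::median(first_lat[hit]) else NA_real_,
       latencies = first_lat[hit])
}

#' Stimulation efficacy across train frequencies
#'
#' @param trains A [spike_train_set()] or list of spike-time vectors.
#' @param protocols Named list of [pulse_protocol()]s (names = frequency
#'   labels, e.g. "4", "8", "16"); >= 2 entries.
#' @param window Evoked window (s).
#' @param threshold Efficacy threshold used for the flag column (default
#'   0.25, the calibration criterion at 16 Hz).
#' @return Data frame: unit_id, frequency, efficacy, median_latency,
#'   below_threshold; plus attribute `"by_frequency"` with per-frequency
#'   means and a monotonicity diagnostic (Spearman rho of efficacy vs
#'   frequency).
#' @export
efficacy_by_frequency <- function(trains, protocols, window = 0.015,
                                  threshold = 0.25) {
  if (inherits(trains, "spike_train_set")) trains <- trains$spike_times
  if (length(protocols) < 2) stop("need protocols for >= 2 frequencies")
  rows <- list()
  for (id in names(trains)) for (fq in names(protocols)) {
    eff <- stimulation_efficacy(trains[[id]], protocols[[fq]], window)
    rows[[length(rows) + 1]] <-
      data.frame(unit_id = id, frequency = as.numeric(fq),
                 efficacy = eff$probability,
                 median_latency = eff$median_latency,
                 below_threshold = eff$probability < threshold)
  }
  tab <- do.call(rbind, rows)
  by_freq <- stats::aggregate(efficacy ~ frequency, tab, mean)
  rho <- if (nrow(by_freq) > 2)
    stats::cor(by_freq$frequency, by_freq$efficacy, method = "spearman")
  else sign(diff(by_freq$efficacy))[1]
  attr(tab, "by_frequency") <- by_freq
  attr(tab, "monotonicity_rho") <- rho
  tab
}
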