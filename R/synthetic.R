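# Synthetic two-region sessions with known ground truth. The generator
# emulates the statistical structure the analyses assume: discontinuous
# Hann-enveloped theta bursts over 1/f background, biphasic sharp waves
# reversing across the pyramidal layer with superimposed ripples, lagged
# directed cross-region drive, and spike trains with von Mises phase
# preference, SPW-gated rate modulation and light-evoked responses.

#' Generator configuration
#'
#' Defaults describe an intermediate/ventral-hippocampus-like neonatal
#' session: 8.1 theta bursts/min of mean duration 3.5 s and 110.6 µV
#' envelope peak, 8.6 sharp waves/min of 223.8 µV on the layer-subtracted
#' trace, units firing at 0.45 Hz with ~20% of units theta-locked.
#'
#' @param duration Session length (s).
#' @param fs Sampling rate (Hz).
#' @param n_channels Hippocampal channel count (>= 3 enables SPW geometry).
#' @param n_channels_pl Prelimbic channel count.
#' @param burst_rate Theta-burst occurrence (events/min).
#' @param burst_duration_mean,burst_duration_sd Burst duration (s).
#' @param burst_peak_amplitude Envelope peak of the burst waveform (µV).
#' @param burst_center_freq Dominant burst frequency (Hz).
#' @param burst_beta_fraction Relative amplitude of the weaker 12-40 Hz
#'   component mixed into each burst (0 disables it).
#' @param burst_envelope Envelope shape, "tukey" (default) or "hann".
#' @param burst_taper_fraction Taper fraction per flank of the Tukey
#'   envelope.
#' @param background_exponent Spectral slope alpha of the 1/f^alpha floor.
#' @param background_rms Background RMS per channel (µV).
#' @param background_shared Fraction of background variance shared across
#'   channels of a region (0 = independent).
#' @param pl_burst_rate Prelimbic burst occurrence (events/min; 0 disables).
#' @param pl_burst_amplitude Prelimbic burst envelope peak (µV).
#' @param spw_rate Sharp-wave occurrence (events/min).
#' @param spw_amplitude SPW peak amplitude on the subtracted
#'   (above - below pyramidal layer) trace (µV).
#' @param spw_width SPW main-deflection Gaussian sigma (s).
#' @param ripple_freq Ripple frequency (Hz).
#' @param ripple_fraction Ripple amplitude relative to the SPW amplitude.
#' @param coupling_gain Gain of the theta-band hippocampus->prelimbic drive
#'   (0 = uncoupled).
#' @param coupling_lag Directed-drive delay (s).
#' @param n_units,n_units_pl Units per region.
#' @param unit_rate Mean single-unit firing rate (Hz).
#' @param locked_fraction Fraction of units phase-locked during bursts.
#' @param locking_kappa von Mises concentration of locked units.
#' @param preferred_phase Preferred theta phase (rad; 0 = LFP peak).
#' @param spw_mod_fraction Fraction of hippocampal units SPW-modulated.
#' @param spw_mod_factor Rate multiplier inside the SPW window.
#' @param spw_mod_window Half-width of the SPW modulation window (s).
#' @param light_response_prob Per-pulse probability that a responsive unit
#'   fires a light-evoked spike.
#' @param light_latency_mean,light_latency_sd Evoked-spike latency (s),
#'   truncated to (0.001, 0.010).
#' @param light_responsive_fraction Fraction of hippocampal units that are
#'   light-responsive.
#' @param stim A [pulse_protocol()] or `NULL`.
#' @param stim_entrain_amplitude Amplitude (µV) of the LFP oscillation at
#'   the train frequency entrained during each stimulation train (0 = none).
#' @param seed Integer seed fixing the full output stream.
#' @return A `generator_config` list.
#' @export
generator_config <- function(duration = 900, fs = 3200,
                             n_channels = 3, n_channels_pl = 1,
                             burst_rate = 8.1,
                             burst_duration_mean = 3.5,
                             burst_duration_sd = 0.1,
                             burst_peak_amplitude = 110.6,
                             burst_center_freq = 8,
                             burst_beta_fraction = 0.2,
                             burst_envelope = c("tukey", "hann"),
                             burst_taper_fraction = 0.25,
                             background_exponent = 1,
                             background_rms = 20,
                             background_shared = 0,
                             pl_burst_rate = 0,
                             pl_burst_amplitude = 50,
                             spw_rate = 8.6,
                             spw_amplitude = 223.8,
                             spw_width = 0.015,
                             ripple_freq = 150,
                             ripple_fraction = 0.2,
                             coupling_gain = 0,
                             coupling_lag = 0.015,
                             n_units = 10, n_units_pl = 10,
                             unit_rate = 0.45,
                             locked_fraction = 0.2,
                             locking_kappa = 2,
                             preferred_phase = 0,
                             spw_mod_fraction = 0.5,
                             spw_mod_factor = 3,
                             spw_mod_window = 0.05,
                             light_response_prob = 0.6,
                             light_latency_mean = 0.005,
                             light_latency_sd = 0.0015,
                             light_responsive_fraction = 0.5,
                             stim = NULL,
                             stim_entrain_amplitude = 0,
                             seed = 1) {
  cfg <- as.list(environment())
  cfg$burst_envelope <- match.arg(burst_envelope)
  stopifnot(cfg$duration > 0, cfg$fs > 0,
            cfg$burst_rate >= 0, cfg$burst_duration_mean >= 0,
            cfg$burst_peak_amplitude >= 0, cfg$spw_rate >= 0,
            cfg$spw_amplitude >= 0, cfg$unit_rate >= 0,
            cfg$coupling_lag >= 0,
            cfg$background_exponent >= 0, cfg$background_exponent <= 2,
            cfg$fs > 2 * max(cfg$burst_center_freq, cfg$ripple_freq))
  structure(cfg, class = "generator_config")
}

#' Colored-noise background recording
#'
#' FFT-shaped Gaussian noise with power spectral density proportional to
#' `1/f^alpha` (flattened below 1 Hz), scaled to the configured RMS, with an
#' optional variance fraction shared across channels.
#'
#' @param cfg A [generator_config()].
#' @param n_channels Channels to generate.
#' @param region Region label.
#' @return A [recording()]. Uses the current RNG stream (seed it upstream).
#' @export
generate_background <- function(cfg, n_channels = cfg$n_channels,
                                region = "ivHP") {
  n <- round(cfg$duration * cfg$fs)
  shape_one <- function() {
    w <- stats::rnorm(n)
    if (cfg$background_exponent == 0) return(w * cfg$background_rms / stats::sd(w))
    f <- c(0, seq_len(n - 1)) * cfg$fs / n
    f <- pmin(f, cfg$fs - f)          # two-sided frequency axis
    g <- 1 / pmax(f, 1)^(cfg$background_exponent / 2)
    g[1] <- 0                          # no DC
    x <- Re(stats::fft(stats::fft(w) * g, inverse = TRUE)) / n
    x * cfg$background_rms / stats::sd(x)
  }
  common <- if (cfg$background_shared > 0) shape_one() else NULL
  samples <- matrix(0, n_channels, n)
  for (ch in seq_len(n_channels)) {
    x <- shape_one()
    if (!is.null(common))
      x <- sqrt(1 - cfg$background_shared) * x +
        sqrt(cfg$background_shared) * common
    samples[ch, ] <- x
  }
  recording(samples, cfg$fs, channel_depths = seq_len(n_channels) * 100,
            region = region)
}

# burst amplitude envelope on u in [0,1]. Tukey (tapered cosine) is the
# default: smooth spindle-like on/offsets over `taper` of the duration at
# each end with a flat plateau, so the burst's extent is operationally
# well defined for threshold detectors. "hann" gives the fully-tapered
# cosine bell.
burst_envelope <- function(u, shape = "tukey", taper = 0.25) {
  if (shape == "hann") return(0.5 * (1 - cos(2 * pi * u)))
  env <- rep(1, length(u))
  lo <- u < taper
  hi <- u > 1 - taper
  env[lo] <- 0.5 * (1 - cos(pi * u[lo] / taper))
  env[hi] <- 0.5 * (1 - cos(pi * (1 - u[hi]) / taper))
  env
}

# draw non-overlapping (start, stop) pairs as a hard-core renewal process:
# exponential free gaps between events with a `margin` of guaranteed
# silence, calibrated so the realized event rate equals `rate_per_min`
# (plain Poisson placement with overlap rejection saturates below the
# configured rate at realistic densities)
draw_events <- function(rate_per_min, duration, dur_mean, dur_sd,
                        margin = 1.0, edge = 2.0) {
  if (rate_per_min <= 0)
    return(data.frame(start = numeric(0), stop = numeric(0)))
  mean_cycle <- 60 / rate_per_min
  mean_free <- mean_cycle - dur_mean - margin
  if (mean_free < 0.2) {
    warning("rate ", rate_per_min, "/min unachievable without overlap; ",
            "using the densest non-overlapping packing (achieved rate ~",
            round(60 / (dur_mean + margin + 0.2), 2), "/min)")
    mean_free <- 0.2
  }
  starts <- numeric(0); stops <- numeric(0)
  # start the cycle at a random phase so event positions are stationary
  t <- edge + stats::runif(1, 0, mean_cycle)
  repeat {
    L <- stats::rnorm(1, dur_mean, dur_sd)
    if (L < max(1.2, dur_mean - 4 * dur_sd)) next
    if (t + L > duration - edge) break
    starts <- c(starts, t); stops <- c(stops, t + L)
    t <- t + L + margin + stats::rexp(1, 1 / mean_free)
  }
  data.frame(start = starts, stop = stops)
}

#' Inject discontinuous theta bursts
#'
#' Adds Hann-enveloped narrow-band bursts (dominant theta carrier plus an
#' optional weaker 12-40 Hz component) at Poisson-placed, non-overlapping
#' times to every channel of `rec`. The composite waveform of each burst is
#' normalized so its envelope peak equals `amplitude`.
#'
#' @param rec Background [recording()].
#' @param cfg A [generator_config()].
#' @param rate,dur_mean,dur_sd,amplitude Override the config's burst
#'   parameters (defaults take them from `cfg`).
#' @return List with the augmented `recording` and a `truth` data frame
#'   (start, stop, duration, amplitude, freq, phase0, beta_freq).
#' @export
inject_theta_bursts <- function(rec, cfg, rate = cfg$burst_rate,
                                dur_mean = cfg$burst_duration_mean,
                                dur_sd = cfg$burst_duration_sd,
                                amplitude = cfg$burst_peak_amplitude) {
  ev <- draw_events(rate, rec_duration(rec), dur_mean, dur_sd)
  fs <- rec$fs
  truth <- data.frame(start = ev$start, stop = ev$stop,
                      duration = ev$stop - ev$start,
                      amplitude = rep(amplitude, nrow(ev)),
                      freq = rep(cfg$burst_center_freq, nrow(ev)),
                      phase0 = stats::runif(nrow(ev), -pi, pi),
                      beta_freq = stats::runif(nrow(ev), 15, 35))
  if (amplitude > 0 && nrow(ev)) {
    for (i in seq_len(nrow(ev))) {
      i0 <- round(truth$start[i] * fs) + 1
      i1 <- round(truth$stop[i] * fs)
      tt <- (seq(i0, i1) - i0) / fs
      L <- truth$duration[i]
      env <- burst_envelope(tt / L, cfg$burst_envelope,
                            cfg$burst_taper_fraction)
      # theta carrier scaled so its own envelope peak equals `amplitude`;
      # the weaker beta-band component rides on top
      w <- amplitude * env *
        (cos(2 * pi * truth$freq[i] * tt + truth$phase0[i]) +
         cfg$burst_beta_fraction * cos(2 * pi * truth$beta_freq[i] * tt))
      rec$samples[, i0:i1] <- sweep(rec$samples[, i0:i1, drop = FALSE], 2,
                                    w, `+`)
    }
  }
  list(recording = rec, truth = truth)
}

# biphasic difference-of-Gaussians SPW waveform, peak-normalized to 1
spw_waveform <- function(fs, sigma1 = 0.015, sigma2 = 0.04) {
  half <- round(4 * sigma2 * fs)
  t <- (-half:half) / fs
  w <- exp(-t^2 / (2 * sigma1^2)) - 0.5 * exp(-t^2 / (2 * sigma2^2))
  w / max(abs(w))
}

#' Inject sharp-wave/ripple complexes
#'
#' Each sharp wave is a biphasic transient of opposite polarity on channels
#' above vs below the pyramidal channel (so the above-minus-below subtracted
#' trace peaks at `amplitude`), with a Gaussian-windowed ripple burst on the
#' pyramidal channel.
#'
#' @param rec Hippocampal [recording()] with >= 3 channels.
#' @param cfg A [generator_config()].
#' @param pyr_channel Pyramidal-layer channel index (default: middle).
#' @param rate,amplitude Override config values.
#' @return List with the augmented `recording`, `truth` data frame
#'   (peak_time, amplitude) and `pyr_channel`.
#' @export
inject_spw_ripples <- function(rec, cfg, pyr_channel = NULL,
                               rate = cfg$spw_rate,
                               amplitude = cfg$spw_amplitude) {
  nch <- nrow(rec$samples)
  if (nch < 3) stop("need >= 3 channels for the above/pyr/below geometry")
  if (is.null(pyr_channel)) pyr_channel <- (nch + 1) %/% 2
  fs <- rec$fs
  dur <- rec_duration(rec)
  # renewal placement with a 0.5 s refractory gap; exponential free gaps
  # calibrated so the realized rate equals `rate` (uniform placement with
  # refractory thinning would undershoot by the thinning probability)
  refr <- 0.5
  mean_free <- max(60 / rate - refr, 0.1)
  peaks <- numeric(0)
  tcur <- 1 + stats::runif(1, 0, 60 / rate)
  repeat {
    if (tcur > dur - 1) break
    peaks <- c(peaks, tcur)
    tcur <- tcur + refr + stats::rexp(1, 1 / mean_free)
  }
  w <- spw_waveform(fs, cfg$spw_width, cfg$spw_width * 8 / 3)
  half <- (length(w) - 1) / 2
  rip_sd <- 0.02
  rip_half <- round(3 * rip_sd * fs)
  rip_t <- (-rip_half:rip_half) / fs
  n <- ncol(rec$samples)
  for (pk in peaks) {
    ip <- round(pk * fs)
    idx <- (ip - half):(ip + half)
    ok <- idx >= 1 & idx <= n
    for (ch in seq_len(nch)) {
      pol <- sign(rec$channel_depths[ch] - rec$channel_depths[pyr_channel])
      if (pol == 0) next
      # depths increase downward: "above" (shallower) gets +, "below" gets -
      rec$samples[ch, idx[ok]] <- rec$samples[ch, idx[ok]] -
        pol * (amplitude / 2) * w[ok]
    }
    ridx <- (ip - rip_half):(ip + rip_half)
    rok <- ridx >= 1 & ridx <= n
    ripple <- cfg$ripple_fraction * amplitude *
      exp(-rip_t^2 / (2 * rip_sd^2)) * cos(2 * pi * cfg$ripple_freq * rip_t)
    rec$samples[pyr_channel, ridx[rok]] <- rec$samples[pyr_channel, ridx[rok]] +
      ripple[rok]
  }
  list(recording = rec,
       truth = data.frame(peak_time = peaks, amplitude = amplitude),
       pyr_channel = pyr_channel)
}

#' Add lagged directed drive from one region to another
#'
#' The theta-band (4-12 Hz) component of the source's first channel,
#' delayed by `lag` and scaled by `gain`, is added to every destination
#' channel. Ground-truth interaction is source -> destination only.
#'
#' @param src,dst [recording()]s sharing fs and duration.
#' @param cfg A [generator_config()].
#' @param gain,lag Override config values.
#' @return The augmented destination `recording`.
#' @export
couple_regions <- function(src, dst, cfg, gain = cfg$coupling_gain,
                           lag = cfg$coupling_lag) {
  if (src$fs != dst$fs || ncol(src$samples) != ncol(dst$samples))
    stop("recordings must share fs and duration")
  if (lag >= rec_duration(src)) stop("lag must be shorter than the recording")
  if (gain == 0) return(dst)
  theta <- bandpass_filter(recording(src$samples[1, , drop = FALSE], src$fs,
                                     region = src$region),
                           band_definition("theta", 4, 12))$samples[1, ]
  k <- round(lag * src$fs)
  delayed <- c(rep(0, k), theta[seq_len(length(theta) - k)])
  dst$samples <- dst$samples + rep(gain, nrow(dst$samples)) %o% delayed
  dst
}

# von Mises sampler (Best & Fisher); kappa = 0 falls back to uniform
rvonmises <- function(n, mu, kappa) {
  if (kappa <= 0) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n); i <- 0
  while (i < n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
      i <- i + 1
      out[i] <- mu + sign(u[3] - 0.5) * acos(f)
    }
  }
  ((out + pi) %% (2 * pi)) - pi
}

#' Generate spike trains with configurable structure
#'
#' Units are homogeneous Poisson at `unit_rate` outside bursts. Locked
#' units fire inside bursts with von Mises phases (concentration
#' `locking_kappa`) around `preferred_phase` of the burst's theta carrier;
#' SPW-modulated units multiply their rate inside a window around SPW
#' peaks; light-responsive units add an evoked spike with probability
#' `light_response_prob` at short (< 10 ms) latency after each pulse.
#'
#' @param cfg A [generator_config()].
#' @param duration Train duration (s).
#' @param n_units Number of units.
#' @param burst_truth Optional burst ground-truth data frame (for locking).
#' @param spw_truth Optional SPW ground-truth data frame.
#' @param protocol Optional [pulse_protocol()].
#' @param region Region label.
#' @return List with the [spike_train_set()] and a per-unit `truth` data
#'   frame (unit_id, locked, kappa, spw_modulated, light_responsive).
#' @export
generate_spike_trains <- function(cfg, duration = cfg$duration,
                                  n_units = cfg$n_units,
                                  burst_truth = NULL, spw_truth = NULL,
                                  protocol = NULL, region = "ivHP") {
  ids <- sprintf("%s_u%03d", region, seq_len(n_units))
  n_locked <- round(cfg$locked_fraction * n_units)
  n_spw <- round(cfg$spw_mod_fraction * n_units)
  n_light <- round(cfg$light_responsive_fraction * n_units)
  truth <- data.frame(unit_id = ids,
                      locked = seq_len(n_units) <= n_locked,
                      kappa = ifelse(seq_len(n_units) <= n_locked,
                                     cfg$locking_kappa, 0),
                      spw_modulated = seq_len(n_units) <= n_spw,
                      light_responsive = seq_len(n_units) <= n_light)
  in_burst <- function(t) {
    if (is.null(burst_truth) || !nrow(burst_truth)) return(rep(FALSE, length(t)))
    out <- rep(FALSE, length(t))
    for (i in seq_len(nrow(burst_truth)))
      out <- out | (t >= burst_truth$start[i] & t <= burst_truth$stop[i])
    out
  }
  trains <- vector("list", n_units)
  for (u in seq_len(n_units)) {
    st <- sort(stats::runif(stats::rpois(1, cfg$unit_rate * duration),
                            0, duration))
    if (truth$locked[u] && !is.null(burst_truth) && nrow(burst_truth)) {
      # replace in-burst spikes by phase-drawn ones at the same mean rate
      st <- st[!in_burst(st)]
      for (i in seq_len(nrow(burst_truth))) {
        L <- burst_truth$duration[i]
        k <- stats::rpois(1, cfg$unit_rate * L)
        if (k == 0) next
        ph <- rvonmises(k, cfg$preferred_phase, cfg$locking_kappa)
        f0 <- burst_truth$freq[i]
        n_cyc <- max(1, floor(L * f0) - 1)
        cyc <- sample.int(n_cyc, k, replace = TRUE)
        # carrier phase theta(t) = 2*pi*f0*(t - start) + phase0; solve for t
        tt <- burst_truth$start[i] +
          ((ph - burst_truth$phase0[i]) %% (2 * pi) + 2 * pi * (cyc - 1)) /
          (2 * pi * f0)
        tt <- tt[tt > burst_truth$start[i] & tt < burst_truth$stop[i]]
        st <- c(st, tt)
      }
    }
    if (truth$spw_modulated[u] && !is.null(spw_truth) && nrow(spw_truth)) {
      extra_rate <- cfg$unit_rate * (cfg$spw_mod_factor - 1)
      for (pk in spw_truth$peak_time) {
        k <- stats::rpois(1, extra_rate * 2 * cfg$spw_mod_window)
        if (k)
          st <- c(st, stats::runif(k, pk - cfg$spw_mod_window,
                                   pk + cfg$spw_mod_window))
      }
    }
    if (truth$light_responsive[u] && !is.null(protocol)) {
      resp <- stats::runif(length(protocol$pulse_onsets)) < cfg$light_response_prob
      lat <- stats::rnorm(sum(resp), cfg$light_latency_mean,
                          cfg$light_latency_sd)
      lat <- pmin(pmax(lat, 0.001), 0.010)
      st <- c(st, protocol$pulse_onsets[resp] + lat)
    }
    st <- sort(st[st >= 0 & st <= duration])
    while (any(duplicated(st)))
      st[duplicated(st)] <- st[duplicated(st)] + 1e-6
    trains[[u]] <- sort(st)
  }
  names(trains) <- ids
  list(spikes = spike_train_set(trains, region = region,
                                recording_duration = duration),
       truth = truth)
}

#' Generate a complete two-region synthetic session
#'
#' Seeds the RNG from `cfg$seed` and composes background, theta bursts,
#' sharp-wave/ripple complexes, directed coupling, spike trains and
#' optional stimulation-entrained activity into a hippocampus + prelimbic
#' session with a full ground-truth registry.
#'
#' @param cfg A [generator_config()].
#' @return List with `hp` and `pl` [recording()]s, `spikes_hp`/`spikes_pl`,
#'   `protocol`, `pyr_channel`, `truth` (bursts_hp, bursts_pl, spws,
#'   units_hp, units_pl, coupling) and `config`.
#' @export
generate_session <- function(cfg) {
  set.seed(cfg$seed)
  hp <- generate_background(cfg, cfg$n_channels, region = "ivHP")
  pl <- generate_background(cfg, cfg$n_channels_pl, region = "PL")
  bh <- inject_theta_bursts(hp, cfg)
  hp <- bh$recording
  bp <- if (cfg$pl_burst_rate > 0)
    inject_theta_bursts(pl, cfg, rate = cfg$pl_burst_rate,
                        amplitude = cfg$pl_burst_amplitude)
  else list(recording = pl, truth = NULL)
  pl <- bp$recording
  sw <- if (cfg$n_channels >= 3 && cfg$spw_rate > 0)
    inject_spw_ripples(hp, cfg)
  else list(recording = hp, truth = data.frame(peak_time = numeric(0),
                                               amplitude = numeric(0)),
            pyr_channel = if (cfg$n_channels >= 3)
              (cfg$n_channels + 1L) %/% 2L else NA_integer_)
  hp <- sw$recording
  pl <- couple_regions(hp, pl, cfg)
  if (!is.null(cfg$stim) && cfg$stim_entrain_amplitude > 0) {
    tax <- rec_times(hp)
    for (s in cfg$stim$train_starts) {
      idx <- which(tax >= s & tax < s + cfg$stim$train_duration)
      if (!length(idx)) next
      tt <- (idx - idx[1]) / hp$fs
      env <- 0.5 * (1 - cos(2 * pi * tt / (length(tt) / hp$fs)))
      wave <- cfg$stim_entrain_amplitude * env *
        cos(2 * pi * cfg$stim$train_frequency * tt)
      pl$samples[, idx] <- sweep(pl$samples[, idx, drop = FALSE], 2, wave, `+`)
    }
  }
  uh <- generate_spike_trains(cfg, burst_truth = bh$truth,
                              spw_truth = sw$truth, protocol = cfg$stim,
                              region = "ivHP")
  up <- generate_spike_trains(cfg, n_units = cfg$n_units_pl,
                              burst_truth = bh$truth, spw_truth = NULL,
                              protocol = NULL, region = "PL")
  list(hp = hp, pl = pl, spikes_hp = uh$spikes, spikes_pl = up$spikes,
       protocol = cfg$stim, pyr_channel = sw$pyr_channel,
       truth = list(bursts_hp = bh$truth, bursts_pl = bp$truth,
                    spws = sw$truth, units_hp = uh$truth, units_pl = up$truth,
                    coupling = list(gain = cfg$coupling_gain,
                                    lag = cfg$coupling_lag,
                                    direction = "ivHP->PL")),
       config = cfg)
}
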