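# Firing rates, SPW-triggered histograms, phase locking, light responses.

test_that("firing_rate is count over duration", {
  expect_equal(firing_rate(seq(1, 59, length.out = 27), 60), 0.45)
  expect_equal(firing_rate(numeric(0), 60), 0)
  expect_error(firing_rate(1:3, 0), "positive")
  # pooled Poisson units converge to the configured rate
  set.seed(211)
  rates <- replicate(50, firing_rate(sort(runif(rpois(1, 0.45 * 900),
                                                0, 900)), 900))
  expect_lt(abs(mean(rates) - 0.45), 0.02)
})

test_that("spw_triggered_psth is flat for Poisson and peaked for modulated", {
  set.seed(221)
  dur <- 1200
  triggers <- seq(20, dur - 20, by = 8)
  # homogeneous Poisson: flat at r within the 99% Poisson band
  r <- 2
  trains <- lapply(1:20, function(i) sort(runif(rpois(1, r * dur), 0, dur)))
  names(trains) <- paste0("u", 1:20)
  p <- spw_triggered_psth(trains, triggers, window = 3, binsize = 0.1)
  expect_lt(abs(mean(p$rate) - r) / r, 0.05)
  n_per_bin <- r * 0.1 * length(triggers) * 20
  # 99.9% band per bin (60 bins are tested jointly)
  band <- stats::qpois(c(5e-4, 1 - 5e-4), n_per_bin) /
    (0.1 * length(triggers) * 20)
  expect_true(all(p$rate >= band[1] & p$rate <= band[2]))
  # x3 modulation in +/-50 ms: central peak ~ 3r
  cfg <- generator_config(duration = dur, unit_rate = r, n_units = 20,
                          locked_fraction = 0, spw_mod_fraction = 1,
                          spw_mod_factor = 3, spw_mod_window = 0.05,
                          seed = 222)
  set.seed(222)
  out <- generate_spike_trains(cfg, spw_truth = data.frame(peak_time = triggers))
  pm <- spw_triggered_psth(out$spikes, triggers, window = 1, binsize = 0.05)
  centre <- abs(pm$bin_centers) < 0.045
  expect_rel_equal(mean(pm$rate[centre]), 3 * r, 0.1)
  flank <- abs(pm$bin_centers) > 0.5
  expect_rel_equal(mean(pm$rate[flank]), r, 0.1)
  expect_error(spw_triggered_psth(trains, triggers[1:5]), ">= 10")
})

test_that("spike_phases follows the peak-zero Hilbert convention", {
  fs <- 1000
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  lfp <- sin(2 * pi * 8 * t)
  peaks <- (which(diff(sign(diff(lfp))) < 0) + 1) / fs
  peaks <- peaks[peaks > 5 & peaks < 55]
  ph <- spike_phases(peaks, lfp, fs = fs)
  expect_lt(max(abs(ph)), 0.1)
  troughs <- peaks + 1 / 16
  pht <- spike_phases(troughs, lfp, fs = fs)
  expect_lt(max(abs(abs(pht) - pi)), 0.1)
  # von Mises kappa=2 around pi/4: circular mean within 10 degrees
  set.seed(231)
  n <- 200
  want <- neocoupler:::rvonmises(n, pi / 4, 2)
  spike_t <- numeric(n)
  for (i in seq_len(n)) {
    cyc <- sample(50:400, 1)
    spike_t[i] <- (cyc + (want[i] + pi / 2) / (2 * pi)) / 8
  }
  # the sine peaks at phase pi/2 of its argument; shift accordingly
  ph2 <- spike_phases(sort(spike_t), lfp, fs = fs)
  mu <- Arg(mean(exp(1i * ph2)))
  expect_lt(abs(Arg(exp(1i * (mu - pi / 4)))), 10 * pi / 180)
  # spikes outside the LFP range are dropped and counted
  phd <- spike_phases(c(1, 2, 100), lfp[1:(10 * fs)], fs = fs)
  expect_equal(attr(phd, "n_dropped"), 1L)
})

test_that("rayleigh_test is calibrated and matches a permutation oracle", {
  # maximal concentration
  rt <- rayleigh_test(rep(1.3, 50))
  expect_equal(rt$R, 1)
  expect_lt(rt$p, 1e-10)
  # type-I error at alpha = 0.05 within [0.03, 0.07] over 1000 units
  set.seed(241)
  pvals <- replicate(1000, rayleigh_test(runif(40, -pi, pi))$p)
  expect_gte(mean(pvals < 0.05), 0.03)
  expect_lte(mean(pvals < 0.05), 0.07)
  # agreement with a permutation/simulation null within 20% relative
  set.seed(242)
  ph <- neocoupler:::rvonmises(60, 0, 0.55)
  obs <- rayleigh_test(ph)
  R0 <- replicate(1e4, rayleigh_test(runif(60, -pi, pi))$R)
  p_perm <- mean(R0 >= obs$R)
  if (p_perm >= 0.001 && p_perm <= 0.2)
    expect_lt(abs(obs$p - p_perm) / p_perm, 0.2)
  # small samples are flagged untested
  expect_true(is.na(rayleigh_test(runif(5, -pi, pi))$p))
})

test_that("locked_fraction counts significant units", {
  res <- data.frame(unit_id = sprintf("u%03d", 1:310),
                    rayleigh_p = c(rep(0.01, 52), rep(0.5, 258)),
                    tested = TRUE)
  lf <- locked_fraction(res)
  expect_equal(lf$n_locked, 52)
  expect_equal(round(lf$fraction, 3), 0.168)
  res$rayleigh_p <- 0.9
  expect_equal(locked_fraction(res)$fraction, 0)
  expect_error(locked_fraction(res[0, ]), "empty")
})

test_that("phase locking recovers the generator's locked fraction", {
  cfg <- generator_config(duration = 900, fs = 500, n_units = 40,
                          unit_rate = 1.2, locked_fraction = 0.25,
                          locking_kappa = 2, burst_rate = 10,
                          spw_rate = 0, n_channels = 1,
                          coupling_gain = 0, seed = 251)
  ses <- suppressWarnings(generate_session(cfg))  # dense bursts: rate warning
  ev <- ses$truth$bursts_hp
  lk <- phase_locking(ses$spikes_hp, ses$hp, events = ev)
  truth <- ses$truth$units_hp
  # strongly locked units detected, unlocked units near the alpha level
  hit <- lk$locked[match(truth$unit_id[truth$locked], lk$unit_id)]
  expect_gte(mean(hit), 0.8)
  fp <- lk$locked[match(truth$unit_id[!truth$locked], lk$unit_id)]
  expect_lte(mean(fp), 0.2)
})

test_that("stimulation_efficacy matches the Poisson closed form", {
  prot <- pulse_protocol(train_frequency = 8, train_duration = 3,
                         inter_train_interval = 6, n_repeats = 30)
  dur <- 30 * 9 + 5
  for (r in c(0.5, 5, 50)) {
    set.seed(260 + r)
    # average over many Poisson trains to meet the 2% tolerance
    probs <- replicate(40, {
      st <- sort(runif(rpois(1, r * dur), 0, dur))
      stimulation_efficacy(st, prot)$probability
    })
    expect_lt(abs(mean(probs) - (1 - exp(-0.015 * r))), 0.02)
  }
  expect_equal(stimulation_efficacy(numeric(0), prot)$probability, 0)
})

test_that("efficacy_by_frequency recovers a falling response profile", {
  protocols <- list(`4` = pulse_protocol(4, t_start = 0),
                    `8` = pulse_protocol(8, t_start = 300),
                    `16` = pulse_protocol(16, t_start = 600))
  probs <- c(`4` = 0.9, `8` = 0.6, `16` = 0.3)
  set.seed(271)
  trains <- lapply(1:12, function(u) {
    st <- numeric(0)
    for (fq in names(protocols)) {
      on <- protocols[[fq]]$pulse_onsets
      hit <- runif(length(on)) < probs[fq]
      st <- c(st, on[hit] + 0.005)
    }
    sort(st)
  })
  names(trains) <- paste0("u", 1:12)
  tab <- efficacy_by_frequency(trains, protocols)
  bf <- attr(tab, "by_frequency")
  for (fq in c(4, 8, 16))
    expect_lt(abs(bf$efficacy[bf$frequency == fq] - probs[as.character(fq)]),
              0.05)
  expect_equal(attr(tab, "monotonicity_rho"), -1)
  expect_true(all(tab$below_threshold[tab$frequency == 16 &
                                      tab$efficacy < 0.25]))
})
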