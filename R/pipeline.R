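# End-to-end orchestration: simulate (or load) -> detect -> spectra ->
# coupling -> spiking -> summary report, with a manifest that fully
# determines a re-run.

sem <- function(x) stats::sd(x) / sqrt(length(x))

#' Run the full analysis pipeline
#'
#' Generates a synthetic session from `config` (or analyzes a supplied
#' session), then runs oscillation and sharp-wave detection, relative
#' power, directed and undirected coupling, phase locking, SPW-triggered
#' firing and (when a protocol is present) stimulation metrics. All
#' tables can be written as CSV plus a JSON manifest.
#'
#' @param config A [generator_config()] (used to simulate) — or pass a
#'   ready-made `session` instead.
#' @param session Optional session list as returned by
#'   [generate_session()].
#' @param out_dir Optional output directory for CSV tables and the
#'   manifest.
#' @param coupling Run the VAR/gPDC stage (slowest stage; default TRUE).
#' @return A `pipeline_report` list with events, spws, spectra, coupling,
#'   spiking, summary and manifest.
#' @export
run_pipeline <- function(config = generator_config(), session = NULL,
                         out_dir = NULL, coupling = TRUE) {
  if (is.null(session)) session <- generate_session(config)
  cfg <- session$config
  hp <- session$hp; pl <- session$pl
  pyr <- session$pyr_channel
  det_ch <- if (!is.na(pyr)) pyr else 1

  events_hp <- detect_oscillations(hp, channel = det_ch)
  thr_hp <- attr(events_hp, "threshold")
  spws <- if (nrow(hp$samples) >= 3 && !is.na(pyr))
    detect_spws(hp, pyr) else NULL

  relpow <- event_relative_power(hp, events_hp, channel = det_ch)

  coup <- NULL
  if (coupling && nrow(events_hp) >= 3) {
    coup <- tryCatch(
      directed_coupling_report(hp$samples[det_ch, ], pl$samples[1, ],
                               hp$fs, events_hp),
      error = function(e) structure(list(error = conditionMessage(e)),
                                    class = "try-error"))
  }
  icoh <- imaginary_coherence(hp$samples[det_ch, ], pl$samples[1, ], hp$fs)

  locking <- phase_locking(session$spikes_pl, hp$samples[det_ch, ],
                           fs = hp$fs, events = events_hp)
  rates <- vapply(session$spikes_hp$spike_times, firing_rate,
                  numeric(1), duration = session$spikes_hp$recording_duration)
  psth <- if (!is.null(spws) && nrow(spws) >= 10)
    spw_triggered_psth(session$spikes_hp, spws$peak_time) else NULL

  stim <- NULL
  if (!is.null(session$protocol)) {
    eff <- vapply(session$spikes_hp$spike_times, function(st)
      stimulation_efficacy(st, session$protocol)$probability, numeric(1))
    stim <- list(efficacy = eff,
                 power = tryCatch(stim_power_modulation(pl, session$protocol),
                                  error = function(e) NULL))
  }

  summary_tab <- data.frame(
    metric = c("osc_rate_per_min", "osc_duration_s", "osc_amplitude_uv",
               "spw_rate_per_min", "spw_amplitude_uv", "unit_rate_hz"),
    mean = c(nrow(events_hp) / rec_duration(hp) * 60,
             mean(events_hp$duration), mean(events_hp$peak_amplitude),
             if (!is.null(spws)) nrow(spws) / rec_duration(hp) * 60 else NA,
             if (!is.null(spws)) mean(spws$amplitude) else NA,
             mean(rates)),
    sem = c(NA, sem(events_hp$duration), sem(events_hp$peak_amplitude),
            NA, if (!is.null(spws)) sem(spws$amplitude) else NA,
            sem(rates)))

  manifest <- list(
    package_version = as.character(utils::packageVersion("neocoupler")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "stim")],
    detection = list(rms_window = 0.2, k = thr_hp$k,
                     threshold_uv = thr_hp$threshold,
                     threshold_method = thr_hp$method,
                     spw_sd = 5, merge_gap_s = 0.2, min_duration_s = 1),
    coupling = if (!is.null(coup) && is.null(coup$error))
      list(analysis_fs = 200, var_orders = coup$var_orders) else NULL)

  report <- structure(list(events = events_hp, spws = spws,
                           relative_power = relpow, coupling = coup,
                           imaginary_coherence = icoh,
                           locking = locking, rates = rates, psth = psth,
                           stim = stim, summary = summary_tab,
                           manifest = manifest),
                      class = "pipeline_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_event_table(events_hp, file.path(out_dir, "oscillatory_events.csv"))
    if (!is.null(spws))
      write_event_table(spws, file.path(out_dir, "spw_events.csv"))
    utils::write.csv(summary_tab, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    utils::write.csv(locking, file.path(out_dir, "phase_locking.csv"),
                     row.names = FALSE)
    if (!is.null(coup) && is.null(coup$error))
      utils::write.csv(as.data.frame(coup$per_band),
                       file.path(out_dir, "gpdc_band_means.csv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Descriptive comparison of two pipeline reports
#'
#' @param report_a,report_b `pipeline_report` objects with matching
#'   summary schemas.
#' @return Data frame: metric, mean_a, mean_b, difference.
#' @export
compare_conditions <- function(report_a, report_b) {
  a <- report_a$summary; b <- report_b$summary
  common <- intersect(a$metric, b$metric)
  if (!length(common)) stop("no common metrics between reports")
  if (!identical(sort(a$metric), sort(b$metric)))
    stop("summary schemas differ between reports")
  a <- a[match(common, a$metric), ]; b <- b[match(common, b$metric), ]
  data.frame(metric = common, mean_a = a$mean, mean_b = b$mean,
             sem_a = a$sem, sem_b = b$sem,
             difference = a$mean - b$mean)
}
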