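# Session container I/O. A session is stored as a plain-text directory:
#   session.json                 metadata: fs, depths, t0, stimulation
#   regions/<name>/lfp.csv       samples x channels matrix (µV)
#   regions/<name>/units.csv     long table: unit_id, spike_time_s
# The layout is deliberately text-only and diff-able; floats round-trip to
# better than 1e-9 relative (17 significant digits).

fmt_num <- function(x) formatC(x, digits = 17, format = "g")

#' Write a session directory
#'
#' @param path Target directory (created; must not exist or be empty).
#' @param recordings List of [recording()] objects (named by region or not;
#'   region labels are taken from the objects).
#' @param spikes Optional list of [spike_train_set()] objects.
#' @param protocol Optional [pulse_protocol()].
#' @return `path`, invisibly.
#' @export
write_session <- function(path, recordings, spikes = list(), protocol = NULL) {
  if (inherits(recordings, "recording")) recordings <- list(recordings)
  if (inherits(spikes, "spike_train_set")) spikes <- list(spikes)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  meta <- list(format = "neocoupler-session", version = 1L, regions = list())
  for (rec in recordings) {
    rdir <- file.path(path, "regions", rec$region)
    dir.create(rdir, recursive = TRUE, showWarnings = FALSE)
    m <- t(rec$samples)
    colnames(m) <- sprintf("ch%02d", seq_len(nrow(rec$samples)))
    utils::write.table(apply(m, 2, fmt_num), file.path(rdir, "lfp.csv"),
                       sep = ",", row.names = FALSE, quote = FALSE)
    meta$regions[[rec$region]] <-
      list(fs = rec$fs, t0 = rec$t0,
           channel_depths = rec$channel_depths,
           n_channels = nrow(rec$samples), n_samples = ncol(rec$samples))
  }
  for (sts in spikes) {
    rdir <- file.path(path, "regions", sts$region)
    dir.create(rdir, recursive = TRUE, showWarnings = FALSE)
    n <- vapply(sts$spike_times, length, integer(1))
    tab <- data.frame(unit_id = rep(sts$unit_ids, n),
                      spike_time_s = fmt_num(unlist(sts$spike_times,
                                                    use.names = FALSE)))
    utils::write.table(tab, file.path(rdir, "units.csv"), sep = ",",
                       row.names = FALSE, quote = FALSE)
    meta$regions[[sts$region]]$recording_duration <- sts$recording_duration
    meta$regions[[sts$region]]$unit_ids <- sts$unit_ids
  }
  if (!is.null(protocol)) {
    meta$stimulation <- list(
      pulse_onsets = protocol$pulse_onsets,
      pulse_width = protocol$pulse_width,
      train_frequency = protocol$train_frequency,
      train_duration = protocol$train_duration,
      inter_train_interval = protocol$inter_train_interval,
      n_repeats = protocol$n_repeats)
  }
  jsonlite::write_json(meta, file.path(path, "session.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

schema_stop <- function(path, what)
  stop("session schema error: missing ", what, " in ", path, call. = FALSE)

#' Read a session directory
#'
#' @param path Directory written by [write_session()].
#' @return List with elements `recordings` (named list of [recording()]),
#'   `spikes` (named list of [spike_train_set()]) and `protocol`
#'   ([pulse_protocol()] or `NULL`).
#' @export
read_session <- function(path) {
  mf <- file.path(path, "session.json")
  if (!file.exists(mf)) schema_stop(path, "session.json")
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (is.null(meta$regions) || !length(meta$regions))
    schema_stop(path, "regions metadata")
  recordings <- list(); spikes <- list()
  for (rg in names(meta$regions)) {
    info <- meta$regions[[rg]]
    lfp_f <- file.path(path, "regions", rg, "lfp.csv")
    if (file.exists(lfp_f)) {
      if (is.null(info$channel_depths))
        schema_stop(path, paste0("regions/", rg, "/channel_depths"))
      if (is.null(info$fs)) schema_stop(path, paste0("regions/", rg, "/fs"))
      m <- as.matrix(utils::read.csv(lfp_f, colClasses = "numeric"))
      dimnames(m) <- NULL
      recordings[[rg]] <- recording(t(m), fs = as.numeric(info$fs),
                                    channel_depths = info$channel_depths,
                                    region = rg,
                                    t0 = if (is.null(info$t0)) 0 else as.numeric(info$t0))
    }
    un_f <- file.path(path, "regions", rg, "units.csv")
    if (file.exists(un_f)) {
      tab <- utils::read.csv(un_f, colClasses = c("character", "numeric"))
      dur <- info$recording_duration
      if (is.null(dur)) {
        if (!is.null(info$fs) && !is.null(info$n_samples))
          dur <- info$n_samples / info$fs
        else schema_stop(path, paste0("regions/", rg, "/recording_duration"))
      }
      ids <- if (!is.null(info$unit_ids)) info$unit_ids else unique(tab$unit_id)
      trains <- lapply(ids, function(id) sort(tab$spike_time_s[tab$unit_id == id]))
      names(trains) <- ids
      spikes[[rg]] <- spike_train_set(trains, region = rg,
                                      recording_duration = dur)
    }
  }
  protocol <- NULL
  if (!is.null(meta$stimulation)) {
    s <- meta$stimulation
    protocol <- pulse_protocol(train_frequency = s$train_frequency,
                               train_duration = s$train_duration,
                               inter_train_interval = s$inter_train_interval,
                               n_repeats = s$n_repeats,
                               pulse_width = s$pulse_width,
                               t_start = s$pulse_onsets[1])
    # preserve the stored onsets verbatim (authoritative over reconstruction)
    protocol$pulse_onsets <- as.numeric(s$pulse_onsets)
  }
  list(recordings = recordings, spikes = spikes, protocol = protocol)
}

#' Write an event table as CSV
#'
#' One row per detected event: region, channel, start_s, stop_s,
#' amplitude_uv (oscillatory events) or peak_time_s/amplitude_uv (SPWs).
#'
#' @param events Data frame of events.
#' @param file Target CSV path.
#' @export
write_event_table <- function(events, file) {
  utils::write.csv(events, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
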