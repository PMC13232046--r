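# Plain-text readers/writers for the pipeline's artefact formats.

#' Write and read spike trains as CSV
#'
#' Long format with header `unit_id,time_s`; times in seconds from
#' recording start. A leading comment line carries the session id, the
#' recording bounds and the full unit roster, so units with no spikes
#' survive the round trip.
#'
#' @param trains A [spike_train_set].
#' @param path Output file.
#' @return `write_spikes_csv` returns `path` invisibly; `read_spikes_csv`
#'   returns a [spike_train_set].
#' @name spikes_csv
NULL

#' @rdname spikes_csv
#' @export
write_spikes_csv <- function(trains, path) {
  stopifnot(inherits(trains, "spike_train_set"))
  df <- data.frame(
    unit_id = rep(names(trains$spike_times), lengths(trains$spike_times)),
    # full double precision so the round trip is lossless
    time_s = sprintf("%.17g", unlist(trains$spike_times, use.names = FALSE))
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# session_id=%s t_start=%.9g t_end=%.9g units=%s",
                     trains$session_id, trains$t_start, trains$t_end,
                     paste(names(trains$spike_times), collapse = ";")), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname spikes_csv
#' @param path Input file written by [write_spikes_csv()].
#' @export
read_spikes_csv <- function(path) {
  header <- readLines(path, n = 1L)
  meta <- regmatches(header, regexec(
    "session_id=(\\S+) t_start=(\\S+) t_end=(\\S+) units=(\\S+)", header))[[1]]
  if (length(meta) != 5L) stop_invalid("not a spikes CSV written by spikedyn")
  df <- utils::read.csv(path, comment.char = "#")
  units <- strsplit(meta[5], ";", fixed = TRUE)[[1]]
  spikes <- split(df$time_s, factor(df$unit_id, levels = units))
  spikes <- lapply(spikes, function(x) sort(as.numeric(x)))
  spike_train_set(spikes, as.numeric(meta[3]), as.numeric(meta[4]),
                  session_id = meta[2])
}

#' Write synchronous events as a BED-like TSV
#'
#' Columns: session, onset_s, offset_s, duration_s, peak_rate_hz.
#'
#' @param events A `sync_events` data.frame from [detect_sync_events()].
#' @param path Output file.
#' @param session Session label for the first column.
#' @export
write_events_tsv <- function(events, path, session = "session1") {
  df <- data.frame(session = rep(session, nrow(events)),
                   onset_s = events$onset, offset_s = events$offset,
                   duration_s = events$duration, peak_rate_hz = events$peak_rate)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a correlation curve as TSV
#'
#' Columns: bin_ms, mean_r, sem_r, n_pairs.
#'
#' @param curve A `correlation_curve` from [pairwise_correlations()].
#' @param path Output file.
#' @export
write_correlation_tsv <- function(curve, path) {
  df <- data.frame(bin_ms = curve$bin_width * 1000, mean_r = curve$mean_r,
                   sem_r = curve$sem_r, n_pairs = curve$n_pairs)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a PSTH as TSV (time_ms, rate)
#'
#' @param psth A [psth].
#' @param path Output file.
#' @export
write_psth_tsv <- function(psth, path) {
  df <- data.frame(time_ms = psth_times(psth) * 1000, rate = psth$values)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a decay-fit result as JSON
#'
#' @param fit A `decay_fit` from [fit_decay()].
#' @param path Output file.
#' @export
write_decay_json <- function(fit, path) {
  jsonlite::write_json(list(
    peak_latency_ms = fit$peak_latency, tau_ms = fit$tau,
    plateau = fit$plateau, peak = fit$peak,
    plateau_peak_ratio = fit$plateau_peak_ratio,
    baseline_rate_hz = fit$baseline_rate, rss = fit$rss,
    converged = fit$converged
  ), path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
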