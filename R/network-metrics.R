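# Synchronous-event detection and bin-size-dependent pairwise correlations.

#' Detect synchronous events in a population rate series
#'
#' An event is a maximal run of bins whose smoothed population rate strictly
#' exceeds the threshold `median(rate) + n_sd * SD(rate)`, both statistics
#' taken over the full series the threshold is applied to. Onset and offset
#' are placed at the outer edges of the first and last supra-threshold bin,
#' so `duration = run length * bin_width`. With `side = "low"` the mirrored
#' quiescence detector (runs below `median - n_sd * SD`) is returned instead.
#'
#' @param rate A [rate_series] (typically 20 ms bins, 80 ms smoothing).
#' @param n_sd Threshold distance from the median in SDs (default 1).
#' @param side `"high"` (synchronous events, default) or `"low"`.
#' @return data.frame of class `sync_events` with columns onset, offset,
#'   duration (s) and peak_rate (Hz); zero rows when no bin crosses the
#'   threshold or the series is constant (SD = 0).
#' @export
detect_sync_events <- function(rate, n_sd = 1, side = c("high", "low")) {
  stopifnot(inherits(rate, "rate_series"))
  side <- match.arg(side)
  v <- rate$values
  if (length(v) < 10L) stop_invalid("rate series must have at least 10 bins")
  s <- stats::sd(v)
  empty <- data.frame(onset = numeric(0), offset = numeric(0),
                      duration = numeric(0), peak_rate = numeric(0))
  class(empty) <- c("sync_events", "data.frame")
  if (s == 0) return(empty)
  theta <- stats::median(v) + if (side == "high") n_sd * s else -n_sd * s
  above <- if (side == "high") v > theta else v < theta
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  if (!any(keep)) return(empty)
  starts <- starts[keep]; ends <- ends[keep]
  onset <- rate$origin + (starts - 1L) * rate$bin_width
  offset <- rate$origin + ends * rate$bin_width
  peak <- mapply(function(a, b) if (side == "high") max(v[a:b]) else min(v[a:b]),
                 starts, ends)
  out <- data.frame(onset = onset, offset = offset,
                    duration = offset - onset, peak_rate = peak)
  class(out) <- c("sync_events", "data.frame")
  out
}

#' Bin-size-dependent pairwise spike-count correlations
#'
#' For each bin width, spike counts are binned per session, z-scored per
#' unit (normalizing for firing rate), and the Pearson correlation is
#' computed for every within-session unit pair. Pair correlations are pooled
#' across sessions and summarized as mean, SEM and pair count per bin width.
#' Pairs involving a constant-count (silent) unit contribute r = 0.
#'
#' @param sessions A [spike_train_set] or list of them.
#' @param bin_widths Bin widths in seconds (default 5, 10, 20, 50, 100,
#'   200 ms).
#' @return data.frame of class `correlation_curve` with columns bin_width,
#'   mean_r, sem_r, n_pairs.
#' @export
pairwise_correlations <- function(sessions,
                                  bin_widths = c(0.005, 0.01, 0.02, 0.05, 0.1, 0.2)) {
  if (inherits(sessions, "spike_train_set")) sessions <- list(sessions)
  if (any(bin_widths <= 0)) stop_invalid("bin widths must be positive")
  usable <- vapply(sessions, function(s) length(s$spike_times) >= 2L, logical(1))
  if (any(!usable)) {
    warning(sum(!usable), " session(s) with fewer than 2 units skipped")
  }
  sessions <- sessions[usable]
  if (length(sessions) == 0L) stop_invalid("no session with at least 2 units")
  rows <- lapply(bin_widths, function(bw) {
    r_all <- unlist(lapply(sessions, function(s) {
      z <- zscore_counts(bin_spikes(s, bw))
      cm <- suppressWarnings(stats::cor(t(z)))
      cm[!is.finite(cm)] <- 0   # constant-count units: r defined as 0
      cm[upper.tri(cm)]
    }))
    data.frame(bin_width = bw, mean_r = mean(r_all),
               sem_r = stats::sd(r_all) / sqrt(length(r_all)),
               n_pairs = length(r_all))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("correlation_curve", "data.frame")
  out
}
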