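#' Construct a set of simultaneously recorded spike trains
#'
#' Container for the sorted units of one recording session. Spike times are
#' in seconds from recording start; each unit's times must be ascending and
#' lie within `[t_start, t_end]`.
#'
#' @param spike_times Named list of numeric vectors, one per unit, each an
#'   ascending sequence of spike times in seconds.
#' @param t_start,t_end Recording bounds in seconds.
#' @param session_id Session label.
#' @return An object of class `spike_train_set`.
#' @examples
#' sts <- spike_train_set(list(u1 = c(0.1, 0.5), u2 = numeric(0)), 0, 1)
#' mean_firing_rates(sts)
#' @export
spike_train_set <- function(spike_times, t_start, t_end, session_id = "session1") {
  if (!is.list(spike_times) || length(spike_times) < 1L) {
    stop_invalid("`spike_times` must be a non-empty list of numeric vectors")
  }
  check_scalar_num(t_start, "t_start")
  check_scalar_num(t_end, "t_end")
  if (t_end <= t_start) stop_invalid("`t_end` must be greater than `t_start`")
  if (is.null(names(spike_times))) {
    names(spike_times) <- sprintf("unit%03d", seq_along(spike_times))
  }
  if (anyDuplicated(names(spike_times))) stop_invalid("unit ids must be unique")
  spike_times <- lapply(spike_times, function(x) {
    x <- as.numeric(x)
    if (is.unsorted(x)) stop_invalid("spike times must be ascending")
    if (length(x) && (x[1] < t_start || x[length(x)] > t_end)) {
      stop_invalid("spike times must lie within [t_start, t_end]")
    }
    x
  })
  structure(
    list(session_id = as.character(session_id), spike_times = spike_times,
         t_start = as.numeric(t_start), t_end = as.numeric(t_end)),
    class = "spike_train_set"
  )
}

#' @export
print.spike_train_set <- function(x, ...) {
  cat(sprintf("<spike_train_set> session %s: %d units, [%.3f, %.3f] s, %d spikes\n",
              x$session_id, length(x$spike_times), x$t_start, x$t_end,
              sum(lengths(x$spike_times))))
  invisible(x)
}

#' Bin spike trains into a units-by-bins count matrix
#'
#' Half-open bins `[origin + j*bw, origin + (j+1)*bw)` starting at the
#' recording start; a trailing partial bin is discarded.
#'
#' @param trains A [spike_train_set].
#' @param bin_width Bin width in seconds (> 0).
#' @return An object of class `binned_counts`: list with `counts`
#'   (units x bins integer matrix), `bin_width`, `origin`.
#' @export
bin_spikes <- function(trains, bin_width) {
  stopifnot(inherits(trains, "spike_train_set"))
  check_scalar_num(bin_width, "bin_width", positive = TRUE)
  origin <- trains$t_start
  n_bins <- floor((trains$t_end - origin) / bin_width + 1e-9)
  if (n_bins < 1L) stop_invalid("recording shorter than one bin")
  counts <- t(vapply(trains$spike_times, function(x) {
    idx <- floor((x - origin) / bin_width) + 1L
    idx <- idx[idx >= 1L & idx <= n_bins]
    tabulate(idx, nbins = n_bins)
  }, integer(n_bins)))
  # vapply on a single-bin session returns a vector; keep matrix orientation
  if (n_bins == 1L) counts <- matrix(counts, ncol = 1L,
                                     dimnames = list(names(trains$spike_times), NULL))
  structure(list(counts = counts, bin_width = bin_width, origin = origin),
            class = "binned_counts")
}

#' Centred moving (boxcar) average
#'
#' Sliding-average smoother with shrunken windows at the edges, so the output
#' has the same length as the input. For even window sizes the window extends
#' one bin further to the left.
#'
#' @param values Numeric vector.
#' @param window Window size in bins (>= 1, <= length(values)).
#' @return Smoothed numeric vector, same length as `values`.
#' @export
moving_average <- function(values, window) {
  window <- check_count(window, "window")
  n <- length(values)
  if (window > n) stop_invalid("`window` must not exceed the series length")
  if (window == 1L) return(as.numeric(values))
  left <- floor(window / 2)
  right <- window - 1L - left
  cs <- c(0, cumsum(as.numeric(values)))
  i <- seq_len(n)
  lo <- pmax(1L, i - left)
  hi <- pmin(n, i + right)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# round a window in seconds to the nearest odd bin count (>= 1)
odd_window_bins <- function(smoothing_window, bin_width) {
  if (smoothing_window <= 0) return(1L)
  w <- max(1L, round(smoothing_window / bin_width))
  if (w %% 2L == 0L) w <- w + 1L
  as.integer(w)
}

#' Smoothed population firing rate
#'
#' Across-unit mean of per-bin firing rates (counts / bin width, Hz), then a
#' centred moving average. The smoothing window is rounded to the nearest odd
#' number of bins so the boxcar is symmetric.
#'
#' @param binned A [binned_counts] object from [bin_spikes()].
#' @param smoothing_window Smoothing window in seconds (0 = no smoothing).
#' @return An object of class `rate_series`: `values` (Hz per bin),
#'   `bin_width`, `smoothing_window`, `origin`.
#' @export
population_rate <- function(binned, smoothing_window = 0) {
  stopifnot(inherits(binned, "binned_counts"))
  check_scalar_num(smoothing_window, "smoothing_window", nonneg = TRUE)
  if (nrow(binned$counts) < 1L) stop_invalid("no units in `binned`")
  rate <- colMeans(binned$counts) / binned$bin_width
  w <- odd_window_bins(smoothing_window, binned$bin_width)
  if (w > 1L) rate <- moving_average(rate, w)
  structure(list(values = rate, bin_width = binned$bin_width,
                 smoothing_window = smoothing_window, origin = binned$origin),
            class = "rate_series")
}

#' Z-score binned counts per unit
#'
#' Each unit's row is centred and scaled to sample SD 1 (n - 1 denominator).
#' Constant rows (zero SD) map to all zeros, so downstream correlations with
#' silent units are defined as 0.
#'
#' @param binned A [binned_counts] object, or a numeric matrix (units x bins).
#' @return Numeric matrix of z-scores, same dimensions as the counts.
#' @export
zscore_counts <- function(binned) {
  m <- if (inherits(binned, "binned_counts")) binned$counts else as.matrix(binned)
  if (ncol(m) < 2L) stop_invalid("need at least 2 bins to z-score")
  mu <- rowMeans(m)
  sdv <- apply(m, 1L, stats::sd)
  z <- (m - mu) / ifelse(sdv > 0, sdv, 1)
  z[sdv == 0, ] <- 0
  z
}

#' Mean firing rate per unit
#'
#' Spike count divided by recording duration, in Hz.
#'
#' @param trains A [spike_train_set].
#' @return Named numeric vector of rates (Hz).
#' @export
mean_firing_rates <- function(trains) {
  stopifnot(inherits(trains, "spike_train_set"))
  dur <- trains$t_end - trains$t_start
  if (dur <= 0) stop_invalid("zero-length recording")
  vapply(trains$spike_times, length, integer(1)) / dur
}

#' Robust outlier screen via the median absolute deviation
#'
#' Flags values whose distance from the median exceeds `threshold` robust
#' SDs, where the robust SD is the MAD scaled by 1.4826 (consistent with the
#' SD under normality). With `scale_mad = FALSE` the raw MAD is used. If the
#' MAD is zero, any value different from the median is flagged.
#'
#' @param values Numeric vector (length >= 3).
#' @param threshold Flagging threshold in robust SDs (default 3).
#' @param scale_mad Scale the MAD by 1.4826 (default TRUE).
#' @return Logical mask, TRUE for outliers.
#' @export
mad_outliers <- function(values, threshold = 3, scale_mad = TRUE) {
  if (length(values) < 3L) stop_invalid("need at least 3 values")
  check_scalar_num(threshold, "threshold", positive = TRUE)
  med <- stats::median(values)
  s <- stats::mad(values, constant = if (scale_mad) 1.4826 else 1)
  if (s == 0) return(values != med)
  abs(values - med) / s > threshold
}
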