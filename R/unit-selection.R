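# Waveform feature extraction and unit classification.

#' Extract trough-to-peak and half-width from an averaged spike waveform
#'
#' For a negative-going extracellular spike: `trough_to_peak` is the time
#' from the global minimum (trough) to the subsequent global maximum, and
#' `half_width` is the full width of the trough lobe at half its absolute
#' amplitude, with the crossings linearly interpolated between samples.
#' With `lobe = "peak"` the half-width is measured on the positive peak
#' lobe instead.
#'
#' @param waveform Numeric voltage samples (>= 8), containing a negative
#'   trough followed by a positive peak.
#' @param sampling_rate Sampling rate, Hz.
#' @param lobe Lobe on which the half-width is measured (default trough).
#' @return List of class `waveform_features` with `trough_to_peak` and
#'   `half_width`, both in ms.
#' @export
waveform_features <- function(waveform, sampling_rate,
                              lobe = c("trough", "peak")) {
  lobe <- match.arg(lobe)
  check_scalar_num(sampling_rate, "sampling_rate", positive = TRUE)
  w <- as.numeric(waveform)
  n <- length(w)
  if (n < 8L) stop_invalid("waveform must have at least 8 samples")
  if (diff(range(w)) == 0) stop_invalid("flat waveform: features undefined")
  i_tr <- which.min(w)
  if (w[i_tr] >= 0 || i_tr >= n) {
    stop_invalid("no negative trough followed by a peak: features undefined")
  }
  after <- w[(i_tr + 1L):n]
  if (max(after) <= 0) {
    stop_invalid("no positive peak after the trough: features undefined")
  }
  i_pk <- i_tr + which.max(after)
  ttp_ms <- (i_pk - i_tr) / sampling_rate * 1000
  hw_ms <- if (lobe == "trough") {
    lobe_half_width(-w, i_tr, sampling_rate)
  } else {
    lobe_half_width(w, i_pk, sampling_rate)
  }
  structure(list(trough_to_peak = ttp_ms, half_width = hw_ms),
            class = "waveform_features")
}

# Full width at half maximum of the lobe around sample `i_ext` of `v`
# (v oriented so the lobe is a positive deflection), linearly interpolated.
lobe_half_width <- function(v, i_ext, sampling_rate) {
  half <- v[i_ext] / 2
  n <- length(v)
  i <- i_ext
  while (i > 1L && v[i - 1L] > half) i <- i - 1L
  t_left <- if (i == 1L) 1 else i - (half - v[i - 1L]) / (v[i] - v[i - 1L])
  j <- i_ext
  while (j < n && v[j + 1L] > half) j <- j + 1L
  t_right <- if (j == n) n else j + (v[j] - half) / (v[j] - v[j + 1L])
  (t_right - t_left) / sampling_rate * 1000
}

#' Classify a unit as putative parvalbumin-expressing (narrow-spiking)
#'
#' TRUE iff `trough_to_peak < 0.7` ms AND `half_width < 0.4` ms, both
#' strict. Such units are conventionally excluded from population
#' response-dynamics analysis.
#'
#' @param features A [waveform_features] object, or a list with
#'   `trough_to_peak` and `half_width` in ms.
#' @param ttp_max,hw_max Classification thresholds, ms.
#' @return Logical scalar.
#' @export
is_putative_pv <- function(features, ttp_max = 0.7, hw_max = 0.4) {
  features$trough_to_peak < ttp_max && features$half_width < hw_max
}

#' Does a unit qualify as a tone-onset neuron?
#'
#' TRUE iff the baseline-subtracted PSTH first reaches 50% of its maximum
#' over the stimulus window within `window_ms` (default 45 ms) of stimulus
#' onset. The crossing time is found on the smoothed PSTH with linear
#' interpolation between bins. A non-positive peak (no response) gives
#' FALSE.
#'
#' @param psth A baseline-subtracted [psth] object.
#' @param window_ms Latency criterion in ms.
#' @return Logical scalar.
#' @export
is_tone_onset <- function(psth, window_ms = 45) {
  stopifnot(inherits(psth, "psth"))
  if (!isTRUE(psth$baseline_subtracted)) {
    stop_invalid("`psth` must be baseline-subtracted")
  }
  on <- psth$stim_onset; off <- psth$stim_offset
  tt <- psth_times(psth)
  in_stim <- tt >= on & tt <= off
  if (!any(in_stim)) stop_invalid("PSTH does not cover the stimulus window")
  peak <- max(psth$values[in_stim])
  if (peak <= 0) return(FALSE)
  cross <- half_peak_crossing(tt[in_stim], psth$values[in_stim], peak / 2)
  if (is.na(cross)) return(FALSE)
  (cross - on) * 1000 <= window_ms
}

# earliest time at which y first reaches `level`, linearly interpolated
half_peak_crossing <- function(t, y, level) {
  idx <- which(y >= level)
  if (length(idx) == 0L) return(NA_real_)
  i <- idx[1]
  if (i == 1L || y[i] == y[i - 1L]) return(t[i])
  t[i - 1L] + (level - y[i - 1L]) / (y[i] - y[i - 1L]) * (t[i] - t[i - 1L])
}

#' Build a unit classification table
#'
#' Applies the waveform classifier and the tone-onset criterion to a set of
#' units; `included` marks units that are tone-onset and not putative PV.
#'
#' @param waveforms List of numeric waveform vectors, one per unit.
#' @param psths List of baseline-subtracted [psth] objects, same order.
#' @param sampling_rate Waveform sampling rate, Hz.
#' @param unit_ids Optional unit labels.
#' @return data.frame with unit_id, trough_to_peak_ms, half_width_ms,
#'   putative_pv, tone_onset, included.
#' @export
classify_units <- function(waveforms, psths, sampling_rate, unit_ids = NULL) {
  stopifnot(length(waveforms) == length(psths))
  if (is.null(unit_ids)) unit_ids <- sprintf("unit%03d", seq_along(waveforms))
  feats <- lapply(waveforms, waveform_features, sampling_rate = sampling_rate)
  pv <- vapply(feats, is_putative_pv, logical(1))
  onset <- vapply(psths, is_tone_onset, logical(1))
  data.frame(
    unit_id = unit_ids,
    trough_to_peak_ms = vapply(feats, `[[`, numeric(1), "trough_to_peak"),
    half_width_ms = vapply(feats, `[[`, numeric(1), "half_width"),
    putative_pv = pv, tone_onset = onset,
    included = onset & !pv
  )
}
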