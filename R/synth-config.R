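# Validated configuration constructors for the synthetic-data generators.

#' Configuration for spontaneous up/down-state population activity
#'
#' Defines an alternating-renewal (up/down state) population in which every
#' unit is an inhomogeneous Poisson process with rate
#' `base_rate * up_gain` during up-states and `base_rate` during down-states.
#'
#' @param n_units Number of units (>= 1).
#' @param duration Recording duration, seconds.
#' @param base_rates Per-unit baseline rate(s) in Hz; recycled to `n_units`.
#' @param up_gain Multiplicative rate gain during up-states (>= 0);
#'   `up_gain = 1` gives a homogeneous Poisson population.
#' @param mean_up_duration,mean_down_duration Mean dwell times, seconds.
#' @param dwell_distribution `"exponential"` (alternating renewal process) or
#'   `"fixed"` (deterministic dwell times, sharp ground truth for
#'   event-duration tests).
#' @param seed Integer seed.
#' @return A `synth_spont_config` list.
#' @export
synth_spont_config <- function(n_units = 30, duration = 600, base_rates = 2,
                               up_gain = 4, mean_up_duration = 0.3,
                               mean_down_duration = 0.7,
                               dwell_distribution = c("exponential", "fixed"),
                               seed = 1L) {
  n_units <- check_count(n_units, "n_units")
  check_scalar_num(duration, "duration", positive = TRUE)
  check_scalar_num(up_gain, "up_gain", nonneg = TRUE)
  check_scalar_num(mean_up_duration, "mean_up_duration", positive = TRUE)
  check_scalar_num(mean_down_duration, "mean_down_duration", positive = TRUE)
  if (!is.numeric(base_rates) || any(base_rates < 0)) {
    stop_invalid("`base_rates` must be non-negative")
  }
  base_rates <- rep_len(as.numeric(base_rates), n_units)
  structure(list(n_units = n_units, duration = duration, base_rates = base_rates,
                 up_gain = up_gain, mean_up_duration = mean_up_duration,
                 mean_down_duration = mean_down_duration,
                 dwell_distribution = match.arg(dwell_distribution),
                 seed = check_count(seed, "seed", min = 0L)),
            class = "synth_spont_config")
}

#' Configuration for evoked single-unit trial responses
#'
#' Defines the trial-wise firing-rate profile of a tone-onset unit:
#' baseline before stimulus onset, rise to `peak_rate` at
#' `stim_onset + peak_latency`, exponential decay towards `plateau_rate`
#' with time constant `decay_tau` until stimulus offset, then relaxation
#' back to baseline with `offset_tau`.
#'
#' @param n_trials Number of trials (study default 150).
#' @param stim_onset,stim_duration Stimulus onset and duration, seconds
#'   (study default 0.5 s white noise).
#' @param trial_duration Total trial length, seconds.
#' @param baseline_rate,peak_rate,plateau_rate Rates in Hz
#'   (`peak_rate >= plateau_rate >= 0`).
#' @param peak_latency Seconds from onset to peak (0 < latency < duration).
#' @param rise_shape `"linear"` or `"exponential"` rise to peak.
#' @param decay_tau Decay time constant, seconds (> 0).
#' @param offset_tau Post-offset relaxation time constant, seconds.
#' @param seed Integer seed.
#' @return A `synth_evoked_config` list.
#' @export
synth_evoked_config <- function(n_trials = 150, stim_onset = 0.5,
                                stim_duration = 0.5, trial_duration = 1.5,
                                baseline_rate = 5, peak_rate = 30,
                                peak_latency = 0.02,
                                rise_shape = c("linear", "exponential"),
                                decay_tau = 0.12, plateau_rate = 8,
                                offset_tau = 0.03, seed = 1L) {
  n_trials <- check_count(n_trials, "n_trials")
  check_scalar_num(stim_onset, "stim_onset", nonneg = TRUE)
  check_scalar_num(stim_duration, "stim_duration", positive = TRUE)
  check_scalar_num(trial_duration, "trial_duration", positive = TRUE)
  check_scalar_num(baseline_rate, "baseline_rate", nonneg = TRUE)
  check_scalar_num(peak_rate, "peak_rate", nonneg = TRUE)
  check_scalar_num(plateau_rate, "plateau_rate", nonneg = TRUE)
  check_scalar_num(decay_tau, "decay_tau", positive = TRUE)
  check_scalar_num(offset_tau, "offset_tau", positive = TRUE)
  if (peak_rate < plateau_rate) {
    stop_invalid("`peak_rate` must be >= `plateau_rate`")
  }
  if (peak_latency <= 0 || peak_latency >= stim_duration) {
    stop_invalid("`peak_latency` must lie strictly inside (0, stim_duration)")
  }
  if (trial_duration < stim_onset + stim_duration) {
    stop_invalid("`trial_duration` must cover the stimulus")
  }
  structure(list(n_trials = n_trials, stim_onset = stim_onset,
                 stim_duration = stim_duration, trial_duration = trial_duration,
                 baseline_rate = baseline_rate, peak_rate = peak_rate,
                 peak_latency = peak_latency, rise_shape = match.arg(rise_shape),
                 decay_tau = decay_tau, plateau_rate = plateau_rate,
                 offset_tau = offset_tau, seed = check_count(seed, "seed", min = 0L)),
            class = "synth_evoked_config")
}

#' Configuration for biphasic spike-waveform templates
#'
#' @param sampling_rate Sampling rate, Hz (default 30 kHz).
#' @param trough_to_peak Trough-to-subsequent-peak interval, ms.
#' @param half_width Full width at half amplitude of the trough lobe, ms.
#' @param amplitude Trough amplitude, arbitrary units.
#' @param noise_sd Additive Gaussian noise SD, same units.
#' @param seed Integer seed.
#' @return A `synth_waveform_config` list.
#' @export
synth_waveform_config <- function(sampling_rate = 30000, trough_to_peak = 0.5,
                                  half_width = 0.25, amplitude = 100,
                                  noise_sd = 0, seed = 1L) {
  check_scalar_num(sampling_rate, "sampling_rate", positive = TRUE)
  check_scalar_num(trough_to_peak, "trough_to_peak", positive = TRUE)
  check_scalar_num(half_width, "half_width", positive = TRUE)
  check_scalar_num(amplitude, "amplitude", positive = TRUE)
  check_scalar_num(noise_sd, "noise_sd", nonneg = TRUE)
  structure(list(sampling_rate = sampling_rate, trough_to_peak = trough_to_peak,
                 half_width = half_width, amplitude = amplitude,
                 noise_sd = noise_sd, seed = check_count(seed, "seed", min = 0L)),
            class = "synth_waveform_config")
}

#' Configuration for synthetic EEG with an injected delta rhythm
#'
#' Signal model: a delta-band sinusoid (plus optional harmonics at integer
#' multiples of its frequency, with amplitude 1/k at the k-th multiple)
#' superimposed on 1/f ("pink") background noise.
#'
#' @param duration Seconds.
#' @param sampling_rate Hz.
#' @param delta_freq Fundamental frequency, Hz, within the 1-4 Hz delta band.
#' @param delta_amplitude Sinusoid amplitude, microvolts.
#' @param pink_noise_amplitude SD of the 1/f background, microvolts.
#' @param harmonics Number of harmonics above the fundamental.
#' @param state_epochs Optional data.frame (state, start, end) of
#'   non-overlapping vigilance-state epochs in seconds.
#' @param seed Integer seed.
#' @return A `synth_eeg_config` list.
#' @export
synth_eeg_config <- function(duration = 120, sampling_rate = 200,
                             delta_freq = 3, delta_amplitude = 50,
                             pink_noise_amplitude = 20, harmonics = 0,
                             state_epochs = NULL, seed = 1L) {
  check_scalar_num(duration, "duration", positive = TRUE)
  check_scalar_num(sampling_rate, "sampling_rate", positive = TRUE)
  check_scalar_num(delta_freq, "delta_freq", positive = TRUE)
  if (delta_freq < 1 || delta_freq > 4) {
    stop_invalid("`delta_freq` must lie in the delta band [1, 4] Hz")
  }
  check_scalar_num(delta_amplitude, "delta_amplitude", nonneg = TRUE)
  check_scalar_num(pink_noise_amplitude, "pink_noise_amplitude", nonneg = TRUE)
  harmonics <- check_count(harmonics, "harmonics", min = 0L)
  if (!is.null(state_epochs)) validate_state_epochs(state_epochs, duration)
  structure(list(duration = duration, sampling_rate = sampling_rate,
                 delta_freq = delta_freq, delta_amplitude = delta_amplitude,
                 pink_noise_amplitude = pink_noise_amplitude,
                 harmonics = harmonics, state_epochs = state_epochs,
                 seed = check_count(seed, "seed", min = 0L)),
            class = "synth_eeg_config")
}

validate_state_epochs <- function(epochs, duration = Inf) {
  if (!is.data.frame(epochs) ||
      !all(c("state", "start", "end") %in% names(epochs))) {
    stop_invalid("`state_epochs` must be a data.frame with state, start, end")
  }
  if (any(epochs$end <= epochs$start)) stop_invalid("epoch end must exceed start")
  if (any(epochs$start < 0) || any(epochs$end > duration + 1e-9)) {
    stop_invalid("epochs must lie within the recording")
  }
  o <- order(epochs$start)
  s <- epochs$start[o]; e <- epochs$end[o]
  if (length(s) > 1L && any(s[-1] < e[-length(e)] - 1e-12)) {
    stop_invalid("state epochs must not overlap")
  }
  invisible(epochs)
}
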