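# Seeded generators for spike trains, evoked trials, waveforms and EEG.

#' Generate spontaneous up/down-state population spike trains
#'
#' Simulates an alternating up/down-state population: the state sequence is
#' an alternating renewal process (exponential or fixed dwell times) that
#' tiles `[0, duration]`, and each unit fires as a Poisson process whose
#' rate is `base_rate * up_gain` in up-states and `base_rate` in down-states.
#' Because the rate is piecewise constant on the dwell intervals, spikes are
#' drawn exactly as homogeneous Poisson samples per interval.
#'
#' @param config A [synth_spont_config].
#' @return List with `trains` (a [spike_train_set]) and `states`
#'   (data.frame state, start, end tiling the recording).
#' @examples
#' out <- gen_spontaneous(synth_spont_config(n_units = 5, duration = 10, seed = 7))
#' out$trains
#' @export
gen_spontaneous <- function(config) {
  stopifnot(inherits(config, "synth_spont_config"))
  set.seed(config$seed)
  states <- draw_state_sequence(config)
  state_gain <- ifelse(states$state == "up", config$up_gain, 1)
  spikes <- vector("list", config$n_units)
  for (u in seq_len(config$n_units)) {
    r <- config$base_rates[u] * state_gain
    len <- states$end - states$start
    n <- stats::rpois(nrow(states), r * len)
    tot <- sum(n)
    if (tot == 0L) { spikes[[u]] <- numeric(0); next }
    t0 <- rep.int(states$start, n)
    dt <- rep.int(len, n)
    spikes[[u]] <- sort(t0 + stats::runif(tot) * dt)
  }
  names(spikes) <- sprintf("unit%03d", seq_len(config$n_units))
  list(
    trains = spike_train_set(spikes, 0, config$duration,
                             session_id = sprintf("synth_seed%d", config$seed)),
    states = states
  )
}

# Alternating state sequence starting in a down-state; last interval
# truncated at `duration` so the intervals exactly partition the recording.
draw_state_sequence <- function(config) {
  start <- numeric(0); end <- numeric(0); lab <- character(0)
  t <- 0; state <- "down"
  means <- c(down = config$mean_down_duration, up = config$mean_up_duration)
  while (t < config$duration) {
    d <- if (config$dwell_distribution == "exponential") {
      stats::rexp(1L, rate = 1 / means[[state]])
    } else {
      means[[state]]
    }
    e <- min(t + d, config$duration)
    start <- c(start, t); end <- c(end, e); lab <- c(lab, state)
    t <- e
    state <- if (state == "down") "up" else "down"
  }
  data.frame(state = lab, start = start, end = end)
}

# Evoked firing-rate profile r(t) for one trial, vectorised over t.
evoked_rate_profile <- function(config, t) {
  on <- config$stim_onset
  t_pk <- on + config$peak_latency
  off <- on + config$stim_duration
  b <- config$baseline_rate; pk <- config$peak_rate
  pl <- config$plateau_rate
  r <- rep(b, length(t))
  rise <- t >= on & t < t_pk
  if (any(rise)) {
    frac <- (t[rise] - on) / config$peak_latency
    r[rise] <- if (config$rise_shape == "linear") {
      b + (pk - b) * frac
    } else {
      # exponential approach with 3 time constants over the rise window
      b + (pk - b) * (1 - exp(-3 * frac)) / (1 - exp(-3))
    }
  }
  decay <- t >= t_pk & t < off
  r[decay] <- pl + (pk - pl) * exp(-(t[decay] - t_pk) / config$decay_tau)
  post <- t >= off
  if (any(post)) {
    r_off <- pl + (pk - pl) * exp(-(off - t_pk) / config$decay_tau)
    r[post] <- b + (r_off - b) * exp(-(t[post] - off) / config$offset_tau)
  }
  pmax(r, 0)
}

#' Generate evoked trial spike times for one unit
#'
#' Spikes are drawn per trial as an inhomogeneous Poisson process with the
#' configured rate profile, sampled by thinning against the profile maximum.
#'
#' @param config A [synth_evoked_config].
#' @return List with `trials` (a `trial_set`: data.frame of trial, time plus
#'   stimulus metadata) and `truth` (the generating parameters).
#' @export
gen_evoked <- function(config) {
  stopifnot(inherits(config, "synth_evoked_config"))
  set.seed(config$seed)
  cfg <- config
  r_max <- max(cfg$baseline_rate, cfg$peak_rate, cfg$plateau_rate)
  if (r_max == 0) {
    spikes <- data.frame(trial = integer(0), time = numeric(0))
  } else {
    n_per_trial <- stats::rpois(cfg$n_trials, r_max * cfg$trial_duration)
    tot <- sum(n_per_trial)
    tt <- stats::runif(tot, 0, cfg$trial_duration)
    keep <- stats::runif(tot) < evoked_rate_profile(cfg, tt) / r_max
    trial <- rep.int(seq_len(cfg$n_trials), n_per_trial)[keep]
    tt <- tt[keep]
    o <- order(trial, tt)
    spikes <- data.frame(trial = trial[o], time = tt[o])
  }
  trials <- structure(
    list(unit_id = sprintf("unit_seed%d", cfg$seed), spikes = spikes,
         n_trials = cfg$n_trials, stim_onset = cfg$stim_onset,
         stim_offset = cfg$stim_onset + cfg$stim_duration,
         trial_duration = cfg$trial_duration),
    class = "trial_set"
  )
  truth <- config[c("baseline_rate", "peak_rate", "peak_latency", "decay_tau",
                    "plateau_rate", "offset_tau")]
  truth$plateau_peak_ratio <-
    ratio_from_rates(config$plateau_rate, config$peak_rate, config$baseline_rate)
  list(trials = trials, truth = truth)
}

# plateau/peak ratio of the baseline-subtracted profile
ratio_from_rates <- function(plateau, peak, baseline) {
  if (peak - baseline <= 0) return(NA_real_)
  (plateau - baseline) / (peak - baseline)
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("<trial_set> unit %s: %d trials, stimulus [%.3f, %.3f] s, %d spikes\n",
              x$unit_id, x$n_trials, x$stim_onset, x$stim_offset, nrow(x$spikes)))
  invisible(x)
}

# Biphasic template: negative Gaussian trough lobe plus a later positive
# lobe. FWHM of the trough lobe = half_width; trough-to-peak separation
# = trough_to_peak. Lobes are narrow relative to their separation, so the
# sampled extrema match the configured features to within one sample.
waveform_template <- function(trough_to_peak, half_width, amplitude,
                              sampling_rate) {
  sigma1 <- half_width / 1000 / (2 * sqrt(2 * log(2)))
  sigma2 <- sigma1
  t_trough <- max(4 * sigma1, 0.4e-3)
  t_peak <- t_trough + trough_to_peak / 1000
  t_end <- t_peak + max(4 * sigma2, 0.5e-3)
  t <- seq(0, t_end, by = 1 / sampling_rate)
  -amplitude * exp(-(t - t_trough)^2 / (2 * sigma1^2)) +
    0.5 * amplitude * exp(-(t - t_peak)^2 / (2 * sigma2^2))
}

#' Generate labelled biphasic spike waveforms
#'
#' Draws `n` average-waveform templates with known narrow-spiking ("pv") or
#' broad-spiking ("broad") labels. Narrow-spiking features are sampled below
#' the 0.7 ms / 0.4 ms classification thresholds and broad-spiking features
#' above them, each offset from the threshold by at least `margin_ms`.
#'
#' @param config A [synth_waveform_config] (supplies sampling rate, amplitude,
#'   noise SD and seed).
#' @param n Number of waveforms.
#' @param label_fractions Named fractions, e.g. `c(pv = 0.5)`; the remainder
#'   are broad-spiking.
#' @param margin_ms Minimum feature distance from the classification
#'   thresholds, ms (default two sample periods).
#' @return List with `waveforms` (list of numeric vectors), `labels`
#'   (character), `features` (data.frame of generating trough_to_peak and
#'   half_width, ms), and `sampling_rate`.
#' @export
gen_waveforms <- function(config, n, label_fractions = c(pv = 0.5),
                          margin_ms = 2000 / config$sampling_rate) {
  stopifnot(inherits(config, "synth_waveform_config"))
  n <- check_count(n, "n", min = 0L)
  sample_period_ms <- 1000 / config$sampling_rate
  if (config$trough_to_peak < 2 * sample_period_ms) {
    stop_invalid("`trough_to_peak` must span at least 2 sample periods")
  }
  set.seed(config$seed)
  if (n == 0L) {
    return(list(waveforms = list(), labels = character(0),
                features = data.frame(trough_to_peak = numeric(0),
                                      half_width = numeric(0)),
                sampling_rate = config$sampling_rate))
  }
  pv_frac <- if ("pv" %in% names(label_fractions)) label_fractions[["pv"]] else 0
  n_pv <- round(n * pv_frac)
  labels <- c(rep("pv", n_pv), rep("broad", n - n_pv))
  ttp <- ifelse(labels == "pv",
                stats::runif(n, 0.30, 0.70 - margin_ms),
                stats::runif(n, 0.70 + margin_ms, 1.40))
  hw <- ifelse(labels == "pv",
               stats::runif(n, 0.15, 0.40 - margin_ms),
               stats::runif(n, 0.40 + margin_ms, 0.80))
  waveforms <- lapply(seq_len(n), function(i) {
    w <- waveform_template(ttp[i], hw[i], config$amplitude, config$sampling_rate)
    if (config$noise_sd > 0) w <- w + stats::rnorm(length(w), 0, config$noise_sd)
    w
  })
  list(waveforms = waveforms, labels = labels,
       features = data.frame(trough_to_peak = ttp, half_width = hw),
       sampling_rate = config$sampling_rate)
}

#' Generate synthetic EEG with an injected delta rhythm
#'
#' Signal = delta sinusoid (amplitude `delta_amplitude`, plus `harmonics`
#' overtones at integer multiples with amplitude 1/k) + 1/f background noise
#' synthesized by spectral shaping of white noise.
#'
#' @param config A [synth_eeg_config].
#' @return An [eeg_recording].
#' @export
gen_eeg <- function(config) {
  stopifnot(inherits(config, "synth_eeg_config"))
  set.seed(config$seed)
  fs <- config$sampling_rate
  n <- round(config$duration * fs)
  t <- (seq_len(n) - 1L) / fs
  x <- config$delta_amplitude * sin(2 * pi * config$delta_freq * t)
  if (config$harmonics > 0L) {
    for (k in seq_len(config$harmonics) + 1L) {
      x <- x + (config$delta_amplitude / k) * sin(2 * pi * k * config$delta_freq * t)
    }
  }
  if (config$pink_noise_amplitude > 0) {
    x <- x + pink_noise(n, fs) * config$pink_noise_amplitude
  }
  eeg_recording(x, fs, state_epochs = config$state_epochs)
}

# 1/f noise via spectral shaping: white Gaussian spectrum scaled by
# 1/sqrt(f), inverse transformed, standardized to unit SD.
pink_noise <- function(n, fs) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- c(1, seq_len(n - 1)) * fs / n          # avoid division by zero at DC
  f <- pmin(f, fs - f + fs / n)               # mirror for negative frequencies
  X <- X / sqrt(f)
  X[1] <- 0
  p <- Re(stats::fft(X, inverse = TRUE)) / n
  as.numeric(scale(p))
}
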