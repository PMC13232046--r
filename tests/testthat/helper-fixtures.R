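# Fixtures built in code: deterministic spike sets, trial sets and PSTHs.

# session with explicitly chosen spike times
toy_session <- function() {
  spike_train_set(
    list(a = c(0.05, 0.15, 0.151), b = c(0.02, 0.12), c = numeric(0)),
    t_start = 0, t_end = 0.2
  )
}

# homogeneous Poisson session (up_gain = 1 makes units independent)
poisson_session <- function(n_units = 10, duration = 60, rate = 5, seed = 1) {
  gen_spontaneous(synth_spont_config(
    n_units = n_units, duration = duration, base_rates = rate,
    up_gain = 1, seed = seed
  ))$trains
}

# trial_set with given per-trial spike times (same in every trial)
fixed_trial_set <- function(times_per_trial, n_trials = 10, stim_onset = 0.5,
                            stim_offset = 1.0, trial_duration = 1.5) {
  structure(list(
    unit_id = "fixed",
    spikes = data.frame(trial = rep(seq_len(n_trials),
                                    each = length(times_per_trial)),
                        time = rep(times_per_trial, n_trials)),
    n_trials = n_trials, stim_onset = stim_onset, stim_offset = stim_offset,
    trial_duration = trial_duration
  ), class = "trial_set")
}

# PSTH object with values chosen directly (for boundary-case tests)
raw_psth <- function(values, bin_width = 0.001, window = c(0, 1.5),
                     stim_onset = 0.5, stim_offset = 1.0,
                     baseline_subtracted = FALSE, normalized = FALSE) {
  spikedyn:::new_psth(values, bin_width, window, n_trials = 1,
                      smoothing_window = 0, stim_onset = stim_onset,
                      stim_offset = stim_offset,
                      baseline_subtracted = baseline_subtracted,
                      normalized = normalized)
}

# noiseless exponential-decay population PSTH on 1 ms bins
model_psth <- function(tau = 0.12, A = 0.2, peak_latency = 0.02,
                       stim_onset = 0.5, stim_offset = 1.0,
                       window = c(0, 1.5)) {
  tt <- seq(window[1] + 0.0005, window[2], by = 0.001)
  t_pk <- stim_onset + peak_latency
  y <- numeric(length(tt))
  rise <- tt >= stim_onset & tt < t_pk
  y[rise] <- (tt[rise] - stim_onset) / peak_latency
  dec <- tt >= t_pk & tt <= stim_offset
  y[dec] <- A + (1 - A) * exp(-(tt[dec] - t_pk) / tau)
  raw_psth(y, window = window, stim_onset = stim_onset,
           stim_offset = stim_offset,
           baseline_subtracted = TRUE, normalized = TRUE)
}

# simulate one evoked population and run the full decay pipeline
simulate_population_fit <- function(tau, plateau_ratio, n_units = 100,
                                    n_trials = 150, seed = 1,
                                    baseline = 5, peak = 30) {
  plateau_rate <- baseline + plateau_ratio * (peak - baseline)
  tsets <- lapply(seq_len(n_units), function(u) {
    gen_evoked(synth_evoked_config(
      n_trials = n_trials, decay_tau = tau, plateau_rate = plateau_rate,
      peak_rate = peak, baseline_rate = baseline,
      seed = spikedyn:::derive_seed(seed, u)
    ))$trials
  })
  evoked_decay_pipeline(tsets)
}
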