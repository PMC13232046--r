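test_that("generators are deterministic given config and seed", {
  cfg <- synth_spont_config(n_units = 4, duration = 20, seed = 9)
  expect_identical(gen_spontaneous(cfg), gen_spontaneous(cfg))
  ecfg <- synth_evoked_config(n_trials = 20, seed = 9)
  expect_identical(gen_evoked(ecfg), gen_evoked(ecfg))
  wcfg <- synth_waveform_config(noise_sd = 5, seed = 9)
  expect_identical(gen_waveforms(wcfg, 10), gen_waveforms(wcfg, 10))
  gcfg <- synth_eeg_config(duration = 10, seed = 9)
  expect_identical(gen_eeg(gcfg), gen_eeg(gcfg))
})

test_that("gen_spontaneous matches Poisson expectations and tiles the recording", {
  # homogeneous 10 Hz for 100 s: count within 3 sd of 1000
  out <- gen_spontaneous(synth_spont_config(
    n_units = 5, duration = 100, base_rates = 10, up_gain = 1, seed = 21))
  counts <- lengths(out$trains$spike_times)
  expect_true(all(abs(counts - 1000) < 3 * sqrt(1000)))

  # zero rate: empty trains
  z <- gen_spontaneous(synth_spont_config(
    n_units = 3, duration = 10, base_rates = 0, seed = 1))
  expect_true(all(lengths(z$trains$spike_times) == 0))

  # state intervals exactly partition [0, duration], for both dwell laws
  for (dd in c("exponential", "fixed")) {
    st <- gen_spontaneous(synth_spont_config(
      n_units = 1, duration = 30, dwell_distribution = dd, seed = 5))$states
    expect_equal(st$start[1], 0)
    expect_equal(st$end[nrow(st)], 30)
    expect_equal(st$start[-1], st$end[-nrow(st)])
  }
  expect_error(synth_spont_config(duration = -1), "duration")
})

test_that("pairwise correlation of generated populations increases with up_gain", {
  m <- vapply(c(1, 2, 4), function(ug) {
    tr <- gen_spontaneous(synth_spont_config(
      n_units = 30, duration = 600, base_rates = 2, up_gain = ug, seed = 31))$trains
    pairwise_correlations(tr, 0.1)$mean_r
  }, numeric(1))
  expect_true(all(diff(m) > 0))
})

test_that("gen_evoked realizes the configured rate profile", {
  cfg <- synth_evoked_config(n_trials = 150, peak_rate = 30, baseline_rate = 5,
                             plateau_rate = 8, seed = 41)
  out <- gen_evoked(cfg)
  t_pk <- cfg$stim_onset + cfg$peak_latency
  sel <- out$trials$spikes$time >= t_pk - 0.005 & out$trials$spikes$time < t_pk + 0.005
  est <- sum(sel) / (150 * 0.01)
  se <- sqrt(30 * 0.01 * 150) / (150 * 0.01)
  expect_lt(abs(est - 30), 3 * se)

  # no rate elevation before onset (causality): pre-onset rate = baseline
  pre <- sum(out$trials$spikes$time < cfg$stim_onset) / (150 * cfg$stim_onset)
  expect_lt(abs(pre - 5), 3 * sqrt(5 / (150 * cfg$stim_onset)))

  # flat profile degenerates to homogeneous Poisson
  flat <- synth_evoked_config(n_trials = 100, peak_rate = 10, baseline_rate = 10,
                              plateau_rate = 10, seed = 42)
  nf <- nrow(gen_evoked(flat)$trials$spikes)
  lam <- 10 * flat$trial_duration * 100
  expect_lt(abs(nf - lam), 3 * sqrt(lam))

  # time-averaged firing over the stimulus equals the profile integral
  tt <- seq(cfg$stim_onset, cfg$stim_onset + cfg$stim_duration, by = 1e-4)
  integral <- mean(spikedyn:::evoked_rate_profile(cfg, tt)) * cfg$stim_duration
  n_stim <- sum(out$trials$spikes$time >= cfg$stim_onset &
                out$trials$spikes$time <= cfg$stim_onset + cfg$stim_duration)
  expect_lt(abs(n_stim / 150 - integral), 3 * sqrt(integral / 150))

  expect_error(synth_evoked_config(peak_rate = 5, plateau_rate = 8), "plateau")
})

test_that("gen_waveforms builds templates whose features match the configuration", {
  cfg <- synth_waveform_config(sampling_rate = 30000, trough_to_peak = 0.5,
                               half_width = 0.25, noise_sd = 0, seed = 51)
  w <- spikedyn:::waveform_template(0.5, 0.25, 100, 30000)
  f <- waveform_features(w, 30000)
  expect_lt(abs(f$trough_to_peak - 0.5), 1000 / 30000 + 1e-9)
  expect_lt(abs(f$half_width - 0.25), 1000 / 30000 + 1e-9)

  expect_equal(length(gen_waveforms(cfg, 0)$waveforms), 0)
  bad <- synth_waveform_config(sampling_rate = 1000, trough_to_peak = 0.5)
  expect_error(gen_waveforms(bad, 5), "sample periods")
})

test_that("gen_eeg concentrates spectral mass as configured", {
  # pure tone: all mass at 3 Hz
  pure <- gen_eeg(synth_eeg_config(duration = 60, delta_freq = 3,
                                   pink_noise_amplitude = 0, seed = 61))
  pr <- stft_psd(pure, normalization = "none")[[1]]
  expect_equal(pr$frequencies[which.max(pr$power)], 3)
  in_peak <- abs(pr$frequencies - 3) <= 0.5
  expect_gt(sum(pr$power[in_peak]) / sum(pr$power), 0.99)

  # no delta component: no peak above the 1/f continuum, so the band max
  # sits at the falling band edge rather than at an interior rhythm
  flatr <- gen_eeg(synth_eeg_config(duration = 120, delta_amplitude = 0,
                                    pink_noise_amplitude = 20, seed = 62))
  pf <- stft_psd(flatr)[[1]]
  expect_lte(band_max(pf, c(1, 4))$frequency, 1.5)
  with_delta <- gen_eeg(synth_eeg_config(duration = 120, delta_amplitude = 50,
                                         pink_noise_amplitude = 20, seed = 62))
  expect_equal(band_max(stft_psd(with_delta)[[1]], c(1, 4))$frequency, 3)

  # overlapping epochs rejected
  ep <- data.frame(state = c("w", "n"), start = c(0, 5), end = c(6, 10))
  expect_error(synth_eeg_config(duration = 10, state_epochs = ep), "overlap")
})
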