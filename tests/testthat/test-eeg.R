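test_that("downsample_eeg decimates with near-lossless passband", {
  t <- (0:(2000 * 20 - 1)) / 2000
  rec <- eeg_recording(sin(2 * pi * 3 * t), 2000)
  d <- downsample_eeg(rec, 200)
  expect_equal(length(rec$samples) / length(d$samples), 10)
  core <- d$samples[601:3400]
  expect_lt(abs(1 - sqrt(2) * sqrt(mean(core^2))), 0.01)

  # identity at equal rates; invalid targets rejected
  expect_identical(downsample_eeg(rec, 2000), rec)
  expect_error(downsample_eeg(rec, 4000), "target")
  expect_error(downsample_eeg(rec, 300), "integer multiple")

  # state epochs (in seconds) survive
  ep <- data.frame(state = "wake", start = 0, end = 20)
  rec2 <- eeg_recording(rec$samples, 2000, state_epochs = ep)
  expect_equal(downsample_eeg(rec2, 200)$state_epochs, ep)
})

test_that("stft_psd localizes tones and satisfies Parseval", {
  pure <- gen_eeg(synth_eeg_config(duration = 60, delta_freq = 3,
                                   pink_noise_amplitude = 0, seed = 131))
  pr <- stft_psd(pure)[[1]]
  expect_equal(pr$frequencies[which.max(pr$power)], 3, tolerance = 0.25)

  # white noise: spectrum flat over 1-40 Hz
  set.seed(132)
  wn <- eeg_recording(rnorm(200 * 600), 200)
  pw <- stft_psd(wn, normalization = "none")[[1]]
  sel <- pw$frequencies >= 1 & pw$frequencies <= 40
  expect_lt(max(pw$power[sel]) / min(pw$power[sel]), 1.5)

  # Parseval: band-integrated power matches time-domain variance
  df <- pw$frequencies[2] - pw$frequencies[1]
  expect_lt(abs(sum(pw$power) * df / var(wn$samples) - 1), 0.05)

  # per-state averaging and omission of too-short states
  ep <- data.frame(state = c("wake", "NREM", "REM"),
                   start = c(0, 30, 59.5), end = c(30, 59.5, 60))
  rec <- gen_eeg(synth_eeg_config(duration = 60, state_epochs = ep, seed = 133))
  expect_warning(pr2 <- stft_psd(rec), "REM")
  expect_setequal(names(pr2), c("wake", "NREM"))
})

test_that("broadband normalization makes profiles gain-invariant", {
  rec <- gen_eeg(synth_eeg_config(duration = 60, seed = 134))
  rec2 <- eeg_recording(5 * rec$samples, rec$sampling_rate)
  p1 <- stft_psd(rec)[[1]]
  p2 <- stft_psd(rec2)[[1]]
  expect_equal(p1$power, p2$power)
  # and the mean over the normalization band is 1
  sel <- p1$frequencies >= 0.75 & p1$frequencies <= 47.75
  expect_equal(mean(p1$power[sel]), 1)
})

test_that("band_max finds the delta maximum inclusively and scales with power", {
  rec <- gen_eeg(synth_eeg_config(duration = 120, delta_freq = 3,
                                  delta_amplitude = 50,
                                  pink_noise_amplitude = 10, seed = 135))
  bm <- band_max(stft_psd(rec)[[1]])
  expect_equal(bm$frequency, 3, tolerance = 0.25)

  # doubling the amplitude quadruples the (unnormalized) band max
  r1 <- gen_eeg(synth_eeg_config(duration = 60, delta_amplitude = 25,
                                 pink_noise_amplitude = 0, seed = 136))
  r2 <- gen_eeg(synth_eeg_config(duration = 60, delta_amplitude = 50,
                                 pink_noise_amplitude = 0, seed = 136))
  m1 <- band_max(stft_psd(r1, normalization = "none")[[1]])$max_power
  m2 <- band_max(stft_psd(r2, normalization = "none")[[1]])$max_power
  expect_equal(m2 / m1, 4, tolerance = 0.01)

  # band edges are inclusive
  edge <- gen_eeg(synth_eeg_config(duration = 60, delta_freq = 4,
                                   pink_noise_amplitude = 0, seed = 137))
  expect_equal(band_max(stft_psd(edge)[[1]], c(1, 4))$frequency, 4)
  expect_error(band_max(stft_psd(edge)[[1]], c(0.01, 0.02)), "no frequency")
})

test_that("harmonic-rich delta rhythm shows local maxima at its overtones", {
  rec <- gen_eeg(synth_eeg_config(duration = 120, delta_freq = 3, harmonics = 2,
                                  delta_amplitude = 50,
                                  pink_noise_amplitude = 10, seed = 138))
  pr <- stft_psd(rec)[[1]]
  local_peak <- function(f0) {
    sel <- abs(pr$frequencies - f0) <= 0.5
    pr$frequencies[sel][which.max(pr$power[sel])]
  }
  expect_equal(local_peak(6), 6)
  expect_equal(local_peak(9), 9)
})
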