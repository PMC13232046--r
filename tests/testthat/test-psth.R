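test_that("build_unit_psth conserves spike mass and normalizes by trials", {
  # one spike at 100 ms in every trial: smoothed bump integrates to 1 spike
  ts <- fixed_trial_set(0.1, n_trials = 20)
  p <- build_unit_psth(ts)
  expect_equal(sum(p$values) * p$bin_width, 1)
  tt <- spikedyn:::psth_times(p)
  expect_lt(abs(tt[which.max(p$values)] - 0.1), 0.011)

  # no spikes: zero PSTH
  empty <- fixed_trial_set(numeric(0), n_trials = 5)
  expect_equal(build_unit_psth(empty)$values, rep(0, 1500))

  # time-mean equals total spikes / (n_trials * span) before smoothing edges
  ge <- gen_evoked(synth_evoked_config(n_trials = 30, seed = 101))
  p2 <- build_unit_psth(ge$trials, smoothing_window = 0)
  expect_equal(mean(p2$values),
               nrow(ge$trials$spikes) / (30 * ge$trials$trial_duration))
  expect_error(build_unit_psth(ge$trials, window = c(1, 1)), "window")
})

test_that("baseline_subtract removes the 200 ms pre-onset mean", {
  tt_n <- 1500
  p <- raw_psth(rep(5, tt_n))
  out <- baseline_subtract(p)
  expect_equal(out$values, rep(0, tt_n))
  expect_equal(out$baseline_rate, 5)
  expect_true(out$baseline_subtracted)

  # baseline 5, peak 30 -> subtracted peak 25; baseline window mean exactly 0
  v <- rep(5, tt_n); v[520:540] <- 30
  out2 <- baseline_subtract(raw_psth(v))
  expect_equal(max(out2$values), 25)
  tt <- spikedyn:::psth_times(out2)
  expect_equal(mean(out2$values[tt >= 0.3 & tt < 0.5]), 0)

  # insufficient pre-stimulus coverage
  short <- raw_psth(rep(1, 100), window = c(0.45, 0.55))
  expect_error(baseline_subtract(short), "baseline")
})

test_that("population_psth averages then peak-normalizes", {
  v <- numeric(1500); v[520:700] <- seq(10, 1, length.out = 181)
  p1 <- raw_psth(v, baseline_subtracted = TRUE)
  p2 <- raw_psth(2 * v, baseline_subtracted = TRUE)
  pop <- population_psth(list(p1, p2))
  expect_equal(max(pop$values), 1)
  expect_true(pop$normalized)
  # identical inputs: common shape scaled to peak 1
  pop1 <- population_psth(list(p1, p1))
  expect_equal(pop1$values, v / max(v))

  # average-then-normalize differs from normalize-then-average (brute force)
  w <- numeric(1500); w[520:700] <- seq(2, 4, length.out = 181)
  p3 <- raw_psth(w, baseline_subtracted = TRUE)
  pooled <- population_psth(list(p1, p3))$values
  other <- (v / max(v) + w / max(w)) / 2
  other <- other / max(other[520:1000])
  expect_gt(max(abs(pooled - other)), 0.01)

  expect_error(population_psth(list(raw_psth(v))), "baseline-subtracted")
  neg <- raw_psth(-v, baseline_subtracted = TRUE)
  expect_error(population_psth(list(neg)), "normalize")
})

test_that("fit_decay recovers noiseless exponential parameters", {
  for (A in c(0, 0.2)) {
    p <- model_psth(tau = 0.12, A = A)
    f <- fit_decay(p)
    expect_true(f$converged)
    expect_lt(abs(f$tau - 120), 1)
    expect_lt(abs(f$plateau_peak_ratio - A), 0.005)
    expect_lt(abs(f$peak_latency - 20), 1)
  }
  # free-peak variant agrees on noiseless data
  ff <- fit_decay(model_psth(tau = 0.12, A = 0.2), free_peak = TRUE)
  expect_lt(abs(ff$tau - 120), 2)

  # refuses un-normalized input and too-short fit windows
  expect_error(fit_decay(raw_psth(rep(1, 1500))), "normalized")
  late <- model_psth(tau = 0.12, A = 0, peak_latency = 0.497)
  expect_error(fit_decay(late), "10 bins")
})

test_that("full pipeline recovers tau and peak latency from simulated units", {
  for (tau in c(0.05, 0.12, 0.25)) {
    out <- simulate_population_fit(tau, 0.2, n_units = 60, n_trials = 150,
                                   seed = 110 + round(1000 * tau))
    expect_lt(abs(out$fit$tau - tau * 1000) / (tau * 1000), 0.15)
    # generator peak latency is 20 ms
    expect_lt(abs(out$fit$peak_latency - 20), 10)
  }
})

test_that("fit_response_profile undoes the smoothing bias of the anchored fit", {
  out <- simulate_population_fit(0.25, 0.4, n_units = 100, n_trials = 150,
                                 seed = 7920)
  anchored <- fit_decay(out$population)
  profiled <- out$fit
  expect_lt(abs(profiled$tau - 250), abs(anchored$tau - 250))
  expect_lt(abs(profiled$peak_latency - 20), 5)
})

test_that("fitted tau increases with the generating decay constant", {
  taus <- vapply(c(0.05, 0.12, 0.25), function(tau) {
    simulate_population_fit(tau, 0.2, n_units = 30, n_trials = 60,
                            seed = 120)$fit$tau
  }, numeric(1))
  expect_true(all(diff(taus) > 0))
})
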