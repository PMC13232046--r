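test_that("bin_spikes counts spikes into half-open bins and drops the partial bin", {
  sts <- toy_session()
  b <- bin_spikes(sts, 0.1)
  expect_equal(unname(b$counts["a", ]), c(1, 2))
  expect_equal(unname(b$counts["c", ]), c(0, 0))    # empty unit: all-zero row

  # conservation: binned + discarded partial bin = total spikes
  sts2 <- spike_train_set(list(u = c(0.01, 0.11, 0.25, 0.28)), 0, 0.29)
  b2 <- bin_spikes(sts2, 0.1)
  n_partial <- sum(sts2$spike_times$u >= b2$origin + ncol(b2$counts) * 0.1)
  expect_equal(sum(b2$counts) + n_partial, 4)
  expect_error(bin_spikes(sts, 0), "bin_width")
})

test_that("moving_average is a centred boxcar with shrunken edges", {
  expect_equal(moving_average(rep(3, 10), 5), rep(3, 10))
  imp <- c(rep(0, 10), 1, rep(0, 10))
  out <- moving_average(imp, 4)
  expect_equal(sum(out > 0), 4)
  expect_equal(unique(out[out > 0]), 0.25)

  # brute-force oracle: mean over the same index window
  set.seed(7)
  x <- rnorm(25)
  for (w in c(1, 3, 4, 7)) {
    brute <- vapply(seq_along(x), function(i) {
      lo <- max(1, i - floor(w / 2)); hi <- min(length(x), i + (w - 1 - floor(w / 2)))
      mean(x[lo:hi])
    }, numeric(1))
    expect_equal(moving_average(x, w), brute)
  }
  expect_error(moving_average(1:3, 4), "length")
})

test_that("population_rate averages unit rates and respects the smoothing window", {
  # 2 units at 10 Hz, 600 s: time-mean within 3 SE of 10 Hz
  sts <- poisson_session(n_units = 2, duration = 600, rate = 10, seed = 2)
  r <- population_rate(bin_spikes(sts, 0.1), 0.4)
  se <- sqrt(10 / (2 * 600))
  expect_lt(abs(mean(r$values) - 10), 3 * se)

  # single unit equals that unit's smoothed rate; zero smoothing = raw mean
  one <- spike_train_set(list(u = c(0.05, 0.15, 0.45)), 0, 1)
  b <- bin_spikes(one, 0.1)
  expect_equal(population_rate(b, 0)$values, unname(b$counts[1, ] / 0.1))
  expect_equal(population_rate(b, 0.3)$values,
               moving_average(unname(b$counts[1, ]) / 0.1, 3))
})

test_that("rate integral round-trips the total spike count", {
  sts <- poisson_session(n_units = 5, duration = 30, rate = 4, seed = 3)
  b <- bin_spikes(sts, 0.05)
  r <- population_rate(b, 0)
  # mean rate x units x duration(binned part) = spikes in the binned span
  expect_equal(sum(r$values) * 0.05 * 5, sum(b$counts))
})

test_that("zscore_counts standardizes rows, zeroes constant rows, is idempotent", {
  m <- rbind(a = c(0, 2, 0, 2), b = c(5, 5, 5, 5))
  z <- zscore_counts(m)
  # hand computation with the sample SD: sd(0,2,0,2) = 2/sqrt(3)
  expect_equal(unname(z["a", ]), c(-1, 1, -1, 1) * sqrt(3) / 2)
  expect_equal(mean(z["a", ]), 0)
  expect_equal(sd(z["a", ]), 1)
  expect_equal(unname(z["b", ]), c(0, 0, 0, 0))
  expect_equal(zscore_counts(z[1, , drop = FALSE]), z[1, , drop = FALSE])
  # affine invariance
  expect_equal(zscore_counts(3 * m + 7), z)
})

test_that("mean_firing_rates divides counts by duration and matches binning", {
  sts <- spike_train_set(list(u = seq(0.5, 599.5, by = 1), v = numeric(0)), 0, 600)
  r <- mean_firing_rates(sts)
  expect_equal(unname(r["u"]), 1)
  expect_equal(unname(r["v"]), 0)
  # invariance to bin width (oracle: counts from bin_spikes)
  sts2 <- poisson_session(n_units = 3, duration = 50, rate = 6, seed = 4)
  expect_equal(unname(mean_firing_rates(sts2)),
               unname(rowSums(bin_spikes(sts2, 0.01)$counts) / 50))
})

test_that("mad_outliers flags by scaled MAD with the documented conventions", {
  # hand computation: median 2.5, MAD 1.0, |100-2.5|/1.4826 = 65.76 > 3
  expect_equal((100 - 2.5) / 1.4826, 65.7628, tolerance = 1e-4)
  expect_equal(mad_outliers(c(1, 2, 3, 100)), c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(mad_outliers(rep(7, 5)), rep(FALSE, 5))
  # zero MAD: anything off the median is flagged
  expect_equal(mad_outliers(c(1, 1, 1, 2)), c(FALSE, FALSE, FALSE, TRUE))
  # standard normal: flagged fraction near 2*pnorm(-3) = 0.27%
  set.seed(5)
  frac <- mean(mad_outliers(rnorm(10000)))
  expect_gt(frac, 0.0005)
  expect_lt(frac, 0.006)
  # affine invariance
  set.seed(6)
  x <- rnorm(50)
  expect_equal(mad_outliers(-2 * x + 3), mad_outliers(x))
  expect_error(mad_outliers(1:2), "3 values")
})
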