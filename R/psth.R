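# PSTH construction and exponential-decay parametrization of the evoked
# population response.

psth_times <- function(psth) {
  psth$window[1] + (seq_along(psth$values) - 0.5) * psth$bin_width
}

new_psth <- function(values, bin_width, window, n_trials, smoothing_window,
                     stim_onset, stim_offset, baseline_subtracted = FALSE,
                     normalized = FALSE, baseline_rate = NA_real_) {
  structure(list(values = as.numeric(values), bin_width = bin_width,
                 window = window, n_trials = n_trials,
                 smoothing_window = smoothing_window,
                 stim_onset = stim_onset, stim_offset = stim_offset,
                 baseline_subtracted = baseline_subtracted,
                 normalized = normalized, baseline_rate = baseline_rate),
            class = "psth")
}

#' @export
print.psth <- function(x, ...) {
  cat(sprintf(paste0("<psth> %d bins of %.0f ms over [%.3f, %.3f] s, %d trials",
                     " (baseline_subtracted=%s, normalized=%s)\n"),
              length(x$values), x$bin_width * 1000, x$window[1], x$window[2],
              x$n_trials, x$baseline_subtracted, x$normalized))
  invisible(x)
}

#' Build a single-unit peri-stimulus time histogram
#'
#' Trial-aligned spike times are binned (default 1 ms), converted to rate
#' (count / (n_trials * bin_width), Hz) and smoothed with a centred sliding
#' average (default 20 ms, rounded to an odd bin count).
#'
#' @param trials A `trial_set` (see [gen_evoked()]), with spike times in
#'   seconds relative to trial start.
#' @param bin_width Bin width, seconds (default 1 ms).
#' @param smoothing_window Sliding-average window, seconds (default 20 ms;
#'   0 disables smoothing).
#' @param window Analysis window `c(start, end)` in trial time; defaults to
#'   the full trial.
#' @return A [psth] object (flags unset).
#' @export
build_unit_psth <- function(trials, bin_width = 0.001, smoothing_window = 0.02,
                            window = NULL) {
  stopifnot(inherits(trials, "trial_set"))
  check_scalar_num(bin_width, "bin_width", positive = TRUE)
  check_scalar_num(smoothing_window, "smoothing_window", nonneg = TRUE)
  if (is.null(window)) window <- c(0, trials$trial_duration)
  if (window[2] <= window[1]) stop_invalid("empty analysis window")
  n_bins <- floor((window[2] - window[1]) / bin_width + 1e-9)
  if (n_bins < 1L) stop_invalid("analysis window shorter than one bin")
  tt <- trials$spikes$time
  idx <- floor((tt - window[1]) / bin_width) + 1L
  idx <- idx[idx >= 1L & idx <= n_bins]
  rate <- tabulate(idx, nbins = n_bins) / (trials$n_trials * bin_width)
  w <- odd_window_bins(smoothing_window, bin_width)
  if (w > 1L) rate <- moving_average(rate, w)
  new_psth(rate, bin_width, window, trials$n_trials, smoothing_window,
           trials$stim_onset, trials$stim_offset)
}

#' Subtract the pre-stimulus baseline from a PSTH
#'
#' The baseline is the mean rate over the `baseline_window` seconds
#' preceding stimulus onset (default 200 ms).
#'
#' @param psth A [psth].
#' @param baseline_window Length of the pre-onset window, seconds.
#' @return The baseline-subtracted [psth]; the subtracted mean is stored in
#'   its `baseline_rate` field.
#' @export
baseline_subtract <- function(psth, baseline_window = 0.2) {
  stopifnot(inherits(psth, "psth"))
  check_scalar_num(baseline_window, "baseline_window", positive = TRUE)
  tt <- psth_times(psth)
  sel <- tt >= psth$stim_onset - baseline_window & tt < psth$stim_onset
  if (sum(sel) < 1L || psth$window[1] > psth$stim_onset - baseline_window + 1e-9) {
    stop_invalid("PSTH does not cover the pre-stimulus baseline window")
  }
  b <- mean(psth$values[sel])
  out <- psth
  out$values <- psth$values - b
  out$baseline_subtracted <- TRUE
  out$baseline_rate <- b
  out
}

#' Average unit PSTHs into a peak-normalized population PSTH
#'
#' Baseline-subtracted unit PSTHs (matched binning) are averaged across
#' units and the average is divided by its maximum over the stimulus
#' window, so the population peak equals 1.
#'
#' @param unit_psths List of baseline-subtracted [psth] objects.
#' @return A normalized [psth]; `baseline_rate` holds the across-unit mean
#'   of the subtracted unit baselines.
#' @export
population_psth <- function(unit_psths) {
  if (length(unit_psths) < 1L) stop_invalid("need at least one unit PSTH")
  ref <- unit_psths[[1]]
  for (p in unit_psths) {
    stopifnot(inherits(p, "psth"))
    if (!isTRUE(p$baseline_subtracted)) {
      stop_invalid("all unit PSTHs must be baseline-subtracted")
    }
    if (length(p$values) != length(ref$values) ||
        p$bin_width != ref$bin_width || !all(p$window == ref$window)) {
      stop_invalid("unit PSTHs must share window and binning")
    }
  }
  avg <- rowMeans(vapply(unit_psths, `[[`, numeric(length(ref$values)), "values"))
  tt <- ref$window[1] + (seq_along(avg) - 0.5) * ref$bin_width
  in_stim <- tt >= ref$stim_onset & tt <= ref$stim_offset
  peak <- max(avg[in_stim])
  if (peak <= 0) stop_invalid("non-positive population peak: cannot normalize")
  new_psth(avg / peak, ref$bin_width, ref$window,
           sum(vapply(unit_psths, `[[`, numeric(1), "n_trials")),
           ref$smoothing_window, ref$stim_onset, ref$stim_offset,
           baseline_subtracted = TRUE, normalized = TRUE,
           baseline_rate = mean(vapply(unit_psths, `[[`, numeric(1),
                                       "baseline_rate")))
}

#' Parametrize the decay of a population PSTH
#'
#' Finds the population peak within the stimulus window (ties broken by the
#' earliest bin) and fits
#' `y(t) = A + (P - A) * exp(-(t - t_peak) / tau)`
#' by bounded nonlinear least squares over `[t_peak, stim_offset]`. The
#' peak value `P` is fixed at the observed peak by default (the population
#' PSTH is peak-normalized, so typically P = 1); `free_peak = TRUE` fits it
#' as a third parameter. The asymptote `A` is bounded below by 0 when
#' `nonneg_asymptote` is TRUE (default), otherwise by -0.5; tau is bounded
#' to [1 ms, 10 s].
#'
#' @param psth A normalized population [psth] (from [population_psth()]).
#' @param nonneg_asymptote Constrain the asymptote to be non-negative.
#' @param free_peak Fit the peak value instead of fixing it.
#' @return List of class `decay_fit`: baseline_rate (Hz), peak_latency (ms),
#'   tau (ms), plateau, peak, plateau_peak_ratio, rss, converged.
#' @export
fit_decay <- function(psth, nonneg_asymptote = TRUE, free_peak = FALSE) {
  stopifnot(inherits(psth, "psth"))
  if (!isTRUE(psth$normalized)) {
    stop_invalid("`psth` must be a peak-normalized population PSTH")
  }
  tt <- psth_times(psth)
  in_stim <- which(tt >= psth$stim_onset & tt <= psth$stim_offset)
  if (length(in_stim) == 0L) stop_invalid("PSTH does not cover the stimulus")
  i_peak <- in_stim[which.max(psth$values[in_stim])]
  t_peak <- tt[i_peak]
  peak_latency_ms <- (t_peak - psth$stim_onset) * 1000
  fit_idx <- which(tt >= t_peak & tt <= psth$stim_offset)
  if (length(fit_idx) < 10L) {
    stop_invalid("fewer than 10 bins between peak and stimulus offset")
  }
  y <- psth$values[fit_idx]
  ts <- tt[fit_idx] - t_peak
  P_obs <- psth$values[i_peak]
  a_lo <- if (nonneg_asymptote) 0 else -0.5
  # initial values: asymptote from the last 50 ms, tau from the 1/e drop
  a0 <- min(max(mean(y[ts >= max(ts) - 0.05]), a_lo), 1)
  target <- a0 + (P_obs - a0) / exp(1)
  i_e <- which(y <= target)
  tau0 <- if (length(i_e)) max(ts[i_e[1]], 1e-3) else max(ts) / 2
  tau0 <- min(max(tau0, 1e-3), 10)
  df <- data.frame(ts = ts, y = y)
  fit <- tryCatch({
    if (free_peak) {
      minpack.lm::nlsLM(y ~ A + (P - A) * exp(-ts / tau), data = df,
                        start = list(A = a0, tau = tau0, P = P_obs),
                        lower = c(a_lo, 1e-3, 0), upper = c(1, 10, 2),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(y ~ A + (P_obs - A) * exp(-ts / tau), data = df,
                        start = list(A = a0, tau = tau0),
                        lower = c(a_lo, 1e-3), upper = c(1, 10),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }, error = function(e) NULL)
  if (is.null(fit)) {
    res <- list(baseline_rate = psth$baseline_rate,
                peak_latency = peak_latency_ms, tau = NA_real_,
                plateau = NA_real_, peak = P_obs,
                plateau_peak_ratio = NA_real_, rss = NA_real_,
                converged = FALSE)
    class(res) <- "decay_fit"
    return(res)
  }
  cf <- stats::coef(fit)
  A <- unname(cf["A"])
  P <- if (free_peak) unname(cf["P"]) else P_obs
  res <- list(baseline_rate = psth$baseline_rate,
              peak_latency = peak_latency_ms,
              tau = unname(cf["tau"]) * 1000,
              plateau = A, peak = P,
              plateau_peak_ratio = A / P,
              rss = sum(stats::residuals(fit)^2),
              converged = isTRUE(fit$convInfo$isConv))
  class(res) <- "decay_fit"
  res
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(paste0("<decay_fit> peak latency %.1f ms, tau %.1f ms, ",
                     "plateau/peak %.3f (converged: %s)\n"),
              x$peak_latency, x$tau, x$plateau_peak_ratio, x$converged))
  invisible(x)
}

#' Smoothing-aware parametrization of the evoked population response
#'
#' Fits the full onset-response profile — linear rise from stimulus onset to
#' a peak, then exponential decay towards an asymptote — convolved with the
#' PSTH's own sliding-average boxcar, by least squares over the stimulus
#' window. Because the model is convolved with the same smoothing kernel
#' that produced the PSTH, the estimates are free of the peak-flattening
#' bias that affects anchoring the decay at the smoothed maximum: the decay
#' time constant is unbiased and the peak latency estimates the underlying
#' (unsmoothed) latency. Several decay starting values are tried and the
#' best least-squares solution kept.
#'
#' @param psth A normalized population [psth] (from [population_psth()]).
#' @param nonneg_asymptote Constrain the asymptote to be non-negative.
#' @return A `decay_fit` (same fields as [fit_decay()]); `peak` is the
#'   fitted underlying peak value and `plateau_peak_ratio = plateau/peak`.
#' @seealso [fit_decay()] for the direct peak-anchored exponential fit.
#' @export
fit_response_profile <- function(psth, nonneg_asymptote = TRUE) {
  stopifnot(inherits(psth, "psth"))
  if (!isTRUE(psth$normalized)) {
    stop_invalid("`psth` must be a peak-normalized population PSTH")
  }
  tt <- psth_times(psth)
  bw <- psth$bin_width
  w <- odd_window_bins(psth$smoothing_window, bw)
  on <- psth$stim_onset; off <- psth$stim_offset
  margin <- max(0.05, (w + 1) * bw)
  ext <- which(tt >= on - margin - 0.05 & tt <= off + margin)
  te <- tt[ext]
  fitwin <- which(te >= on & te <= off)
  if (length(fitwin) < 10L) {
    stop_invalid("fewer than 10 bins in the stimulus window")
  }
  y <- psth$values[ext][fitwin]
  kern <- rep(1 / w, w)
  model <- function(lat, P, A, ltau) {
    tau <- exp(ltau)
    t_pk <- on + lat
    g <- numeric(length(te))
    r <- te >= on & te < t_pk
    g[r] <- P * (te[r] - on) / lat
    d <- te >= t_pk
    g[d] <- A + (P - A) * exp(-(te[d] - t_pk) / tau)
    stats::filter(g, kern, sides = 2)[fitwin]
  }
  in_stim <- which(tt >= on & tt <= off)
  i_pk <- in_stim[which.max(psth$values[in_stim])]
  lat0 <- min(max(tt[i_pk] - on - bw * (w %/% 2), 0.005), 0.15)
  a_lo <- if (nonneg_asymptote) 0 else -0.5
  a0 <- min(max(mean(psth$values[tt >= off - 0.05 & tt <= off]), a_lo), 1)
  obj <- function(p) {
    m <- model(p[1], p[2], p[3], p[4])
    if (anyNA(m)) return(1e10)
    sum((y - m)^2)
  }
  best <- NULL
  for (tau0 in c(0.05, 0.1, 0.2)) {
    o <- tryCatch(
      stats::optim(c(lat0, 1.05, a0, log(tau0)), obj, method = "L-BFGS-B",
                   lower = c(0.002, 0.5, a_lo, log(1e-3)),
                   upper = c(0.2, 2, 1, log(10))),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) {
    res <- list(baseline_rate = psth$baseline_rate, peak_latency = NA_real_,
                tau = NA_real_, plateau = NA_real_, peak = NA_real_,
                plateau_peak_ratio = NA_real_, rss = NA_real_,
                converged = FALSE)
    class(res) <- "decay_fit"
    return(res)
  }
  res <- list(baseline_rate = psth$baseline_rate,
              peak_latency = best$par[1] * 1000,
              tau = exp(best$par[4]) * 1000,
              plateau = best$par[3], peak = best$par[2],
              plateau_peak_ratio = best$par[3] / best$par[2],
              rss = best$value,
              converged = best$convergence == 0)
  class(res) <- "decay_fit"
  res
}

#' Run the full evoked-response pipeline on a set of units
#'
#' Convenience chain: per-unit PSTH, baseline subtraction, peak-normalized
#' population PSTH, decay parametrization. The default `"profile"` method
#' uses the smoothing-aware fit ([fit_response_profile()]); `"peak"` anchors
#' the exponential at the observed smoothed peak ([fit_decay()]).
#'
#' @param trial_sets List of `trial_set` objects (one per unit).
#' @param bin_width,smoothing_window,baseline_window See the stage functions.
#' @param method Decay parametrization method.
#' @param ... Passed to the chosen fit function.
#' @return List with `unit_psths`, `population` and `fit`.
#' @export
evoked_decay_pipeline <- function(trial_sets, bin_width = 0.001,
                                  smoothing_window = 0.02,
                                  baseline_window = 0.2,
                                  method = c("profile", "peak"), ...) {
  method <- match.arg(method)
  unit_psths <- lapply(trial_sets, function(ts) {
    baseline_subtract(build_unit_psth(ts, bin_width, smoothing_window),
                      baseline_window)
  })
  pop <- population_psth(unit_psths)
  fit <- if (method == "profile") fit_response_profile(pop, ...)
         else fit_decay(pop, ...)
  list(unit_psths = unit_psths, population = pop, fit = fit)
}
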