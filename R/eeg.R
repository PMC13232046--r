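# EEG container, anti-aliased downsampling, per-state Welch/Hamming PSD
# profiles and delta-band maxima.

#' Construct an EEG recording
#'
#' @param samples Numeric signal in microvolts.
#' @param sampling_rate Sampling rate, Hz.
#' @param channel Channel label (`"frontal"`, `"parietal"` or `"other"`).
#' @param state_epochs Optional data.frame (state, start, end) of
#'   non-overlapping vigilance-state epochs, seconds.
#' @return Object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, sampling_rate,
                          channel = c("other", "frontal", "parietal"),
                          state_epochs = NULL) {
  check_scalar_num(sampling_rate, "sampling_rate", positive = TRUE)
  samples <- as.numeric(samples)
  if (length(samples) < 2L) stop_invalid("`samples` must be a signal")
  if (!is.null(state_epochs)) {
    validate_state_epochs(state_epochs, length(samples) / sampling_rate)
  }
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 channel = match.arg(channel), state_epochs = state_epochs),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s channel, %.1f s at %g Hz, %d state epoch(s)\n",
              x$channel, length(x$samples) / x$sampling_rate, x$sampling_rate,
              if (is.null(x$state_epochs)) 0L else nrow(x$state_epochs)))
  invisible(x)
}

#' Downsample an EEG recording with anti-alias filtering
#'
#' Zero-phase FIR low-pass filtering (cutoff at 80% of the target Nyquist
#' frequency, applied forward and backward so the passband has unity gain
#' and no phase distortion) followed by decimation. The decimation factor
#' must be an integer. State epochs, given in seconds, are preserved.
#'
#' @param recording An [eeg_recording].
#' @param target Target sampling rate, Hz (default 200).
#' @return The downsampled [eeg_recording].
#' @export
downsample_eeg <- function(recording, target = 200) {
  stopifnot(inherits(recording, "eeg_recording"))
  check_scalar_num(target, "target", positive = TRUE)
  fs <- recording$sampling_rate
  if (target > fs) stop_invalid("`target` must not exceed the sampling rate")
  if (target == fs) return(recording)
  q <- fs / target
  if (abs(q - round(q)) > 1e-9) {
    stop_invalid("sampling_rate must be an integer multiple of `target`")
  }
  q <- round(q)
  b <- signal::fir1(64, 0.8 / q)
  b <- b / sum(b)   # exact unity DC gain
  y <- signal::filtfilt(signal::Ma(b), recording$samples)
  y <- y[seq(1L, length(y), by = q)]
  eeg_recording(y, target, recording$channel, recording$state_epochs)
}

#' Per-state PSD profiles via Hamming-windowed short-time Fourier transform
#'
#' Within each vigilance state, the signal is cut into `window_length`-second
#' segments with fractional `overlap`, each segment is demeaned, Hamming
#' windowed and Fourier transformed, and the one-sided segment periodograms
#' are averaged (Welch estimate per state). With the default `"broadband"`
#' policy, power is normalized so that the mean power over `norm_band`
#' (0.75-47.75 Hz) across all states equals 1, making profiles invariant to
#' global gain changes; `"total-per-state"` normalizes each state by its own
#' band mean, `"none"` returns physical units (uV^2/Hz).
#'
#' @param recording An [eeg_recording]; without `state_epochs` the whole
#'   signal is treated as one state `"all"`.
#' @param window_length Segment length, seconds (default 4 s, i.e. 0.25 Hz
#'   resolution).
#' @param overlap Fractional segment overlap in `[0, 1)` (default 0.5).
#' @param normalization Power normalization policy.
#' @param norm_band Frequency band (Hz) over which the normalization mean is
#'   taken.
#' @return Named list of `psd_profile` objects (frequencies, power, state),
#'   one per state with at least one full window; states without a full
#'   window are omitted with a warning.
#' @export
stft_psd <- function(recording, window_length = 4, overlap = 0.5,
                     normalization = c("broadband", "none", "total-per-state"),
                     norm_band = c(0.75, 47.75)) {
  stopifnot(inherits(recording, "eeg_recording"))
  normalization <- match.arg(normalization)
  check_scalar_num(window_length, "window_length", positive = TRUE)
  if (overlap < 0 || overlap >= 1) stop_invalid("`overlap` must be in [0, 1)")
  fs <- recording$sampling_rate
  L <- round(window_length * fs)
  step <- max(1L, round(L * (1 - overlap)))
  w <- hamming_window(L)
  U <- sum(w^2)
  n_freq <- floor(L / 2) + 1L
  freqs <- (seq_len(n_freq) - 1L) * fs / L
  epochs <- recording$state_epochs
  if (is.null(epochs)) {
    epochs <- data.frame(state = "all", start = 0,
                         end = length(recording$samples) / fs)
  }
  profiles <- list()
  for (st in unique(epochs$state)) {
    segs <- list()
    for (k in which(epochs$state == st)) {
      i0 <- floor(epochs$start[k] * fs) + 1L
      i1 <- min(floor(epochs$end[k] * fs), length(recording$samples))
      pos <- i0
      while (pos + L - 1L <= i1) {
        segs[[length(segs) + 1L]] <- recording$samples[pos:(pos + L - 1L)]
        pos <- pos + step
      }
    }
    if (length(segs) == 0L) {
      warning("state '", st, "' has no full window; omitted")
      next
    }
    pxx <- rowMeans(vapply(segs, function(s) {
      xw <- (s - mean(s)) * w
      X <- stats::fft(xw)[seq_len(n_freq)]
      p <- (Mod(X)^2) / (fs * U)
      # one-sided: double interior bins (not DC; not Nyquist when L even)
      dbl <- seq(2L, n_freq - if (L %% 2L == 0L) 1L else 0L)
      p[dbl] <- 2 * p[dbl]
      p
    }, numeric(n_freq)))
    profiles[[st]] <- structure(
      list(frequencies = freqs, power = pxx, state = st,
           normalization = normalization),
      class = "psd_profile")
  }
  if (length(profiles) == 0L) stop_invalid("no state has a full window")
  if (normalization != "none") {
    in_band <- freqs >= norm_band[1] & freqs <= norm_band[2]
    if (!any(in_band)) stop_invalid("`norm_band` contains no frequency bin")
    if (normalization == "broadband") {
      ref <- mean(vapply(profiles, function(p) mean(p$power[in_band]),
                         numeric(1)))
      profiles <- lapply(profiles, function(p) { p$power <- p$power / ref; p })
    } else {
      profiles <- lapply(profiles, function(p) {
        p$power <- p$power / mean(p$power[in_band]); p
      })
    }
  }
  profiles
}

hamming_window <- function(n) {
  0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1L) / (n - 1L))
}

#' Maximum PSD within a frequency band
#'
#' Returns the maximum normalized power over the band (edges inclusive) and
#' the frequency at which it occurs. The default band is the 1-4 Hz delta
#' band.
#'
#' @param profile A `psd_profile` from [stft_psd()].
#' @param band Numeric `c(low, high)` in Hz.
#' @return List with `max_power` and `frequency` (Hz).
#' @export
band_max <- function(profile, band = c(1, 4)) {
  stopifnot(inherits(profile, "psd_profile"))
  if (length(band) != 2L || band[2] < band[1]) stop_invalid("invalid `band`")
  sel <- profile$frequencies >= band[1] & profile$frequencies <= band[2]
  if (!any(sel)) stop_invalid("band contains no frequency bin")
  i <- which(sel)[which.max(profile$power[sel])]
  list(max_power = profile$power[i], frequency = profile$frequencies[i])
}
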