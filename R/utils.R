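# Internal helpers: argument checking and seed derivation.

stop_invalid <- function(...) {
  stop(..., call. = FALSE)
}

check_scalar_num <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid("`", name, "` must be a single finite number")
  }
  if (positive && x <= 0) stop_invalid("`", name, "` must be > 0")
  if (nonneg && x < 0) stop_invalid("`", name, "` must be >= 0")
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < min) {
    stop_invalid("`", name, "` must be an integer >= ", min)
  }
  invisible(as.integer(x))
}

# Deterministic sub-seed stream: a Lehmer-style hop keeps derived seeds
# within the 32-bit integer range while decorrelating consecutive offsets.
derive_seed <- function(seed, offset) {
  s <- (as.double(seed) %% 2147483646) + 1
  o <- as.double(offset) %% 2147483646
  as.integer(((s * 48271) %% 2147483647 + o * 69621) %% 2147483646 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
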