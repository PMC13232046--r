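# Bootstrap over neuron sets, repeat-averaged one-sided permutation tests,
# and bin-wise rank-sum comparison of unit PSTHs.

resample_collection <- function(x, idx) {
  if (is.list(x)) x[idx] else x[idx]
}

#' Bootstrap a statistic over a set of units
#'
#' Each replicate draws `length(units)` units with replacement and
#' recomputes `statistic` on the resampled set — the resampling unit is the
#' neuron, matching box plots built over `n` recorded neurons. Replicates on
#' which the statistic errors or returns a non-finite value are recorded as
#' missing; more than 10% failures is an error.
#'
#' @param units Vector or list of per-unit data (values, PSTHs, trial sets).
#' @param statistic Function of a unit set returning a numeric scalar
#'   (e.g. the population-PSTH decay tau).
#' @param n_boot Number of bootstrap sets (study default 1000).
#' @param seed Integer seed.
#' @return List of class `bootstrap_result`: `samples` (length `n_boot`,
#'   NA for failed replicates), `point_estimate`, `quantiles` (2.5, 25, 50,
#'   75, 97.5%), `n_failed`, `seed`.
#' @export
bootstrap_units <- function(units, statistic, n_boot = 1000, seed = 1L) {
  if (length(units) < 2L) stop_invalid("need at least 2 units")
  n_boot <- check_count(n_boot, "n_boot")
  stopifnot(is.function(statistic))
  set.seed(seed)
  n <- length(units)
  samples <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    v <- tryCatch(statistic(resample_collection(units, idx)),
                  error = function(e) NA_real_)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) NA_real_ else v
  }, numeric(1))
  n_failed <- sum(is.na(samples))
  if (n_failed > 0.1 * n_boot) {
    stop_invalid("statistic failed on more than 10% of bootstrap replicates")
  }
  structure(list(
    samples = samples,
    point_estimate = statistic(units),
    quantiles = stats::quantile(samples, c(0.025, 0.25, 0.5, 0.75, 0.975),
                                na.rm = TRUE),
    n_failed = n_failed, seed = seed
  ), class = "bootstrap_result")
}

#' One-sided permutation test with repeat averaging
#'
#' Tests the difference `statistic(group_a) - statistic(group_b)` by
#' shuffling group labels. Each run draws `n_perm` permutations and computes
#' the one-sided add-one p-value
#' `p = (1 + #\{permuted >= observed\}) / (n_perm + 1)` for
#' `side = "greater"` (mirrored for `"less"`); the test is repeated
#' `repeats` times with deterministic sub-seeds and the run p-values are
#' averaged. The direction must be stated explicitly; it is never defaulted.
#'
#' @param group_a,group_b Unit-level values (numeric vectors) or unit sets
#'   (lists).
#' @param statistic Function of one group returning a numeric scalar
#'   (default [mean] for numeric groups).
#' @param side `"greater"` or `"less"` — the tested direction of
#'   `statistic(A) - statistic(B)`.
#' @param n_perm Permutations per run (study default 1000).
#' @param repeats Number of averaged runs (study default 10).
#' @param seed Integer master seed.
#' @return List of class `permutation_result`: `observed_stat`, `p_per_run`,
#'   `p_mean`, `n_perm`, `side`, `seed`.
#' @export
permutation_test <- function(group_a, group_b, statistic = mean,
                             side = c("greater", "less"),
                             n_perm = 1000, repeats = 10, seed = 1L) {
  side <- match.arg(side)
  if (length(group_a) < 1L || length(group_b) < 1L) {
    stop_invalid("both groups must be non-empty")
  }
  n_perm <- check_count(n_perm, "n_perm")
  repeats <- check_count(repeats, "repeats")
  stopifnot(is.function(statistic))
  n_a <- length(group_a)
  pool <- if (is.list(group_a) || is.list(group_b)) {
    c(as.list(group_a), as.list(group_b))
  } else {
    c(group_a, group_b)
  }
  n <- length(pool)
  observed <- statistic(group_a) - statistic(group_b)
  run_seeds <- vapply(seq_len(repeats), function(i) derive_seed(seed, i),
                      integer(1))
  degenerate <- FALSE
  p_per_run <- vapply(seq_len(repeats), function(r) {
    set.seed(run_seeds[r])
    perm <- vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(n, n_a)
      statistic(resample_collection(pool, idx)) -
        statistic(resample_collection(pool, -idx))
    }, numeric(1))
    if (stats::sd(perm) == 0) degenerate <<- TRUE
    exceed <- if (side == "greater") sum(perm >= observed) else sum(perm <= observed)
    (1 + exceed) / (n_perm + 1)
  }, numeric(1))
  if (degenerate) {
    warning("degenerate permutation distribution (all permuted values identical)")
  }
  structure(list(observed_stat = observed, p_per_run = p_per_run,
                 p_mean = mean(p_per_run), n_perm = n_perm, side = side,
                 seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> observed %.4g, side %s, p_mean %.4g (%d runs x %d perms)\n",
              x$observed_stat, x$side, x$p_mean, length(x$p_per_run), x$n_perm))
  invisible(x)
}

#' Bin-wise two-group comparison of unit PSTHs
#'
#' Wilcoxon rank-sum test per time bin on the unit-level PSTH values of two
#' groups; bins with `p < alpha` are flagged (uncorrected, as in bin-wise
#' significance markers on population PSTH figures).
#'
#' @param unit_psths_a,unit_psths_b Lists of [psth] objects with matched
#'   binning, or numeric units-x-bins matrices.
#' @param alpha Significance level (default 0.05).
#' @return data.frame with time_s (NA for plain matrices), p, significant.
#' @export
binwise_compare <- function(unit_psths_a, unit_psths_b, alpha = 0.05) {
  check_scalar_num(alpha, "alpha", positive = TRUE)
  as_mat <- function(x) {
    if (is.matrix(x)) return(x)
    t(vapply(x, `[[`, numeric(length(x[[1]]$values)), "values"))
  }
  a <- as_mat(unit_psths_a); b <- as_mat(unit_psths_b)
  if (nrow(a) < 2L || nrow(b) < 2L) stop_invalid("need >= 2 units per group")
  if (ncol(a) != ncol(b)) stop_invalid("groups must share binning")
  time_s <- if (is.matrix(unit_psths_a)) rep(NA_real_, ncol(a))
            else psth_times(unit_psths_a[[1]])
  p <- vapply(seq_len(ncol(a)), function(j) {
    suppressWarnings(stats::wilcox.test(a[, j], b[, j], exact = FALSE)$p.value)
  }, numeric(1))
  p[is.na(p)] <- 1   # identical constant bins: no evidence of a difference
  data.frame(time_s = time_s, p = p, significant = p < alpha)
}
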