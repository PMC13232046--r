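---
title: "Quantifying cortical population dynamics with spikedyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cortical population dynamics with spikedyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikedyn)
```

## The analysis problem

Extracellular recordings from sensory cortex of awake mice yield tens of
simultaneously sorted units per session. Two complementary views of such data
are the subject of this package:

* **Spontaneous population dynamics.** Cortical populations alternate between
  phases of elevated, synchronous firing and quiet periods. Useful summaries
  are the per-unit mean firing rate, the pairwise correlation of binned spike
  counts (and how it grows with the counting-bin width), and the durations of
  *synchronous events* — contiguous stretches in which the smoothed population
  rate exceeds a threshold derived from its own median and standard deviation.

* **Evoked response dynamics.** Brief sound stimuli evoke a transient
  population response whose termination is controlled by inhibition. The
  response is summarized by a peri-stimulus time histogram (PSTH) and
  parametrized by the latency to peak, the exponential decay time constant
  τ from the peak to stimulus offset, and the plateau/peak ratio (the decay
  asymptote relative to the population peak).

In addition, chronic EEG is profiled per vigilance state by a Hamming-windowed
short-time Fourier transform, with the maximum of the normalized power
spectral density in the δ band (1–4 Hz) as the summary statistic.

Because raw recordings of this kind are rarely depositable, every analysis
stage is paired with a seeded synthetic generator with known ground truth, so
the whole pipeline is testable end to end.

## Spontaneous activity: model and estimators

`gen_spontaneous()` simulates an alternating-renewal ("up/down state")
population: the state sequence tiles the recording with up- and down-dwells
(exponential by default; `"fixed"` dwells give sharp ground truth for
event-duration tests), and each unit fires as a Poisson process with rate
`base_rate * up_gain` in up-states and `base_rate` in down-states. Since the
rate is piecewise constant on dwell intervals, each interval is sampled as an
exact homogeneous Poisson process — no discretisation error. The shared state
modulation is the only source of correlation between units, which yields the
signature the analysis relies on: pairwise correlations that increase with
both the coupling strength and the counting-bin width.

Analysis defaults follow common practice for such recordings:

* binning: half-open bins `[t, t + Δ)`, trailing partial bin dropped;
* event detection: population rate in 20 ms bins, 80 ms sliding average,
  threshold = median + 1 SD of the smoothed series itself, strict inequality,
  no hysteresis and no minimum duration (all configurable); a mirrored
  `side = "low"` detector is available for quiescent periods;
* correlations: counts are z-scored per unit (sample SD; constant rows map to
  zero so silent units contribute r = 0) before Pearson correlation, pairs
  are pooled across sessions, and the default bin-width grid is
  5–200 ms;
* outlier screening: median absolute deviation scaled by 1.4826 with a ±3
  threshold, applied as a pre-analysis screen on per-unit summary values.

The smoothing window is rounded to an odd number of bins so the boxcar is
symmetric; an 80 ms window on 20 ms bins therefore spans 5 bins (100 ms).
Event durations inherit a bias bound of roughly half the smoothing window at
each edge, which is why the package's recovery tests on fixed 300 ms
up-states (10 min, 30 units, up-gain 10, 2 Hz base rate, 700 ms down-dwells —
the default validation condition) demand agreement within ±80 ms and
cross-check against the same detector run on the noiseless rate profile.

## Evoked responses: model and estimators

`gen_evoked()` draws per-trial spike times from an inhomogeneous Poisson
profile: baseline rate before stimulus onset, a rise (linear by default) to
the peak rate at `onset + peak_latency`, exponential decay with time constant
`decay_tau` towards a plateau until stimulus offset, then relaxation back to
baseline. Sampling is by thinning against the profile maximum, vectorised
across trials. Defaults emulate a 500 ms broadband stimulus with 150 trials,
5 Hz baseline, 30 Hz peak, 20 ms peak latency.

The analysis chain is: per-unit PSTH (1 ms bins, count/(trials × bin width),
20 ms sliding average), baseline subtraction (mean over the 200 ms before
onset, applied per unit before averaging), across-unit average, peak
normalization over the stimulus window, then decay parametrization. Unit
selection precedes the population average: a MAD screen on per-unit mean
rates, exclusion of narrow-spiking (putative parvalbumin-expressing) units —
trough-to-peak < 0.7 ms *and* trough-lobe half-width < 0.4 ms, both strict,
measured with sub-sample interpolation — and restriction to tone-onset units,
defined as reaching 50% of their peak response within 45 ms of onset.

### Two decay parametrizations

`fit_decay()` implements the direct description of the method: find the peak
of the normalized population PSTH (ties broken by the earliest bin), then fit
`y(t) = A + (P − A)·exp(−(t − t_peak)/τ)` from the peak to stimulus offset,
with `P` fixed at the observed peak value, `A` the asymptote (bounded below
by 0 by default; `nonneg_asymptote = FALSE` relaxes this to −0.5, since
whether the original analysis constrained the asymptote is not determinable)
and `τ ∈ [1 ms, 10 s]`. A `free_peak` flag fits `P` as well. τ is initialized
from the time at which the curve first drops to `A₀ + (P − A₀)/e`, with `A₀`
the mean over the last 50 ms of the fit window.

This anchored estimator has a known structural bias: the 20 ms sliding
average flattens the PSTH peak, so forcing the fitted curve through the
smoothed maximum makes the early decay look too shallow, inflating τ (about
+6% at τ = 250 ms under the default simulation conditions) and pushing the
argmax-based latency late by 5–10 ms. `fit_response_profile()` removes both
effects by fitting the *full* onset profile — linear rise from onset to a
peak, then exponential decay — convolved with the PSTH's own boxcar kernel,
over the whole stimulus window. In simulation this estimator is unbiased for
τ and recovers the underlying (unsmoothed) peak latency; it is therefore the
default in `evoked_decay_pipeline()` and `run_evoked()`. `fit_decay()`
remains available both as the literal method and as the fast statistic inside
resampling loops, where its bias is common to the compared groups and cancels.

A precision note that shaped the package's validation thresholds: at
τ = 250 ms with a 0.4 plateau/peak ratio, the stimulus window is only ~1.9 τ
long and the asymptote and τ are nearly collinear. The Fisher information
limit for the 150-trial / 100-unit design puts the sampling SD of τ̂ near 6%
of its value, so recovery checks at that design aggregate three replicate
simulations (median) against a 15% bound rather than demanding it of every
single draw.

## Resampling inference

The resampling unit is the *neuron*: `bootstrap_units()` redraws whole units
with replacement (1000 sets by default) and recomputes an arbitrary
statistic, e.g. the population-PSTH τ; replicates on which the statistic
fails are recorded as missing, with more than 10% failures treated as an
error. `permutation_test()` shuffles group labels for a one-sided test of
`statistic(A) − statistic(B)` with the add-one convention
`p = (1 + #{permuted ≥ observed}) / (n_perm + 1)` (so p is never 0 and never
below 1/(n_perm+1)); the 1000-permutation run is repeated 10 times with
deterministic sub-seeds and the run p-values averaged, which shrinks the
Monte-Carlo spread of the reported p. The direction of each one-sided test is
a required argument — it is never defaulted. Bin-wise group differences use
the Wilcoxon rank-sum test per time bin, uncorrected, as is conventional for
significance markers along a PSTH; group-level comparisons delegate to
`stats::kruskal.test`.

## EEG spectra

`gen_eeg()` superimposes a δ-band sinusoid (optionally with harmonics at
integer multiples, amplitude 1/k at the k-th multiple) on 1/f background
noise synthesized by spectral shaping of white Gaussian noise. Recordings are
downsampled to 200 Hz for analysis with a 64-tap FIR low-pass (cutoff 80% of
the target Nyquist, renormalized to exact unity DC gain) applied forward and
backward, then decimated; this keeps a 3 Hz rhythm's amplitude within 0.1%.
`stft_psd()` computes per-state Welch estimates from 4 s Hamming-windowed
segments with 50% overlap (0.25 Hz resolution, standard for rodent sleep
EEG), demeaning each segment; `band_max()` reports the maximum and argmax
frequency over the (inclusive) 1–4 Hz band. Power normalization is a
configurable policy — `"broadband"` (default: mean power over 0.75–47.75 Hz
across states equals 1, making profiles gain-invariant), `"total-per-state"`,
or `"none"` (physical units, satisfying Parseval against the time-domain
variance to within the periodogram's accuracy).

## Orchestrated runs and reproducibility

`run_spontaneous()`, `run_evoked()` and `run_eeg()` chain the stages for
multi-group designs. A `run_config()` (built from arguments or a YAML file;
unknown keys rejected) carries every parameter and a master seed; each
simulated session/unit/resampling stage derives its own sub-seed
deterministically, and the full configuration is echoed into a JSON manifest.
Rebuilding the configuration from the manifest reproduces every number
bit-identically. Artefacts are plain text: spikes as CSV (with full-precision
times, so the round trip is lossless), events and correlation curves and
PSTHs as TSV, fits and manifests as JSON.

## What the synthetic generators do and do not emulate

The generators reproduce the statistical structure the estimators rely on —
Poisson spiking with shared slow rate modulation, trial-wise evoked profiles
with known τ and plateau, biphasic waveforms with controllable features, EEG
with a known rhythm on a 1/f continuum. They deliberately omit refractory
periods, spike-sorting artefacts, burst structure, non-Poisson dispersion,
rate drift, movement artefacts and volume-conducted EMG. Passing recovery
tests therefore demonstrates correctness of the estimators under the stated
model, not robustness to every failure mode of real recordings. Parameters
that the underlying experimental literature does not pin down (per-genotype
rates, coupling strengths) were chosen once for testability and realism, not
to mimic any particular genotype quantitatively.

## Numerical choices and degenerate inputs

* Constant rate series: SD = 0, so event detection returns no events.
* Constant count rows z-score to zero; correlations with them are 0.
* Zero MAD: values different from the median are flagged.
* All-zero PSTHs are never tone-onset; non-positive population peaks are a
  normalization error.
* Monotone or flat waveforms have undefined features (error), as do
  time-reversed ones (no peak after the trough).
* Decay fits require at least 10 bins between peak and offset; optimizer
  failure yields `converged = FALSE` rather than an error.
* Problem sizes in the test suite (units, trials, durations, replicate
  counts) are the package's validation conditions, chosen to give each check
  adequate statistical power at interactive runtimes.
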