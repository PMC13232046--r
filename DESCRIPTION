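Package: spikedyn
Title: Population Spike-Train and EEG Dynamics Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of in-vivo cortical population dynamics from
    extracellular spike trains and EEG: detection of synchronous events in
    the smoothed population firing rate, bin-size-dependent pairwise
    spike-count correlations, spike-waveform classification of putative
    fast-spiking interneurons, peri-stimulus time histogram construction
    and exponential-decay parametrization of evoked responses, bootstrap
    and permutation inference over neuron sets, and delta-band power
    spectral density profiling of EEG by vigilance state. Includes seeded
    synthetic-data generators (up/down-state spike trains, evoked trial
    responses, biphasic waveforms, EEG with an injected delta rhythm) so
    every stage of the pipeline can be validated against known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    signal,
    minpack.lm
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
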