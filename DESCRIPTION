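Package: sparseconn
Title: Synaptic Connectivity Screening and Oscillation Analysis for
    Multi-Neuron Patch-Clamp Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying sparse intrinsic synaptic connectivity
    from multi-neuron whole-cell recordings: trial-averaged screening of
    chemical connections from action-potential train protocols,
    gap-junction coupling coefficients from current steps, template-based
    detection of spontaneous and optogenetically evoked postsynaptic
    currents with a presynaptic-count estimator built on their amplitude
    ratio, and spectrogram band-power analysis of light-ramp induced
    network oscillations. Includes a deterministic slice-electrophysiology
    simulator with known ground truth for calibrating and validating every
    stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, signal, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'trace.R'
    'cells.R'
    'session-io.R'
    'sim-config.R'
    'sim-membrane.R'
    'sim-sessions.R'
    'pairwise-screen.R'
    'pairwise-coupling.R'
    'pairwise-tables.R'
    'events-detect.R'
    'events-stats.R'
    'spectral.R'
    'report.R'
    'utils.R'
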