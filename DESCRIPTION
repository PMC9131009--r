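Package: gammaphase
Title: Gamma Oscillation and Spike-Phase Coupling Analysis for Hippocampal Slice Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for pharmacologically induced gamma oscillations
    (20-80 Hz) recorded as local field potentials in hippocampal slices, and for
    the phase-locking of parvalbumin interneuron spikes to those oscillations.
    Provides band-pass filtering and Welch spectral estimation with slice
    inclusion (quality-control) rules, the coefficient of rhythmicity from
    autocorrelograms, CA3-CA1 cross-correlation peak and delay, cell-attached
    spike detection with half-width and inter-spike-interval metrics,
    interictal-like event detection, instantaneous gamma phase and first-order
    (Rayleigh) plus second-order (Hotelling one-sample, Batschelet two-sample)
    circular statistics of spike-phase coupling, cohort-level contingency
    analysis of CA1 gamma participation, and a seeded synthetic-data generator
    emulating two-channel slice recordings with phase-locked spike trains.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
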