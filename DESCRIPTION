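Package: phaselock
Title: Phase-Based EEG Synchrony and Connectivity During Response Inhibition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for studying cortical phase synchronization during
    response inhibition in the auditory stop-signal paradigm. Simulates
    the stop-signal task with a 1-up/1-down stop-signal-delay staircase
    and an independent race model, estimates the stop-signal reaction
    time (SSRT), and generates seeded 32-channel synthetic EEG whose
    across-trial phase concentration and between-channel phase coupling
    are user-controlled ground truth. Provides zero-phase Butterworth
    band-pass filtering and epoch handling, complex Morlet time-frequency
    decomposition with inter-trial coherence (ITC) and Rayleigh-test
    significance masks, Hilbert-transform instantaneous phase and
    phase-locking value (PLV) connectivity over standard 10-20 electrode
    pairs with trial-shuffled surrogate nulls, connectivity-graph
    construction against a pre-stimulus baseline, European Data Format
    (EDF) input/output, and a reproducible end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
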