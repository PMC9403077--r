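Package: icohnet
Title: Task-Based EEG Cortical Network Analysis with Imaginary Coherency
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for task-based electroencephalography
    (EEG) functional cortical network analysis on a 68-region cortical
    parcellation. Implements sensor-space preprocessing (common average
    reference, zero-phase Butterworth band-pass, epoching, amplitude-based
    epoch rejection, principal-component region summaries), single-Hanning-
    taper time-frequency total power with pre-stimulus baseline
    normalization, imaginary-coherency connectomes for baseline and task
    windows, task-specific enhanced and diminished weighted networks,
    weighted graph indices (strength, Onnela clustering coefficient,
    characteristic path length), Welch two-sample tests with pooled effect
    sizes, cluster-based permutation tests, and permutation Pearson
    correlation. A synthetic-data module simulates auditory-oddball cohorts
    with phase-lagged theta coupling and symptom scores so the whole
    pipeline is testable without access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    signal,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
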