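Package: ieegpipe
Title: Headless Spectral Power Analysis Pipeline for Intracranial EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A headless analysis pipeline for intracranial
    electroencephalography (iEEG/ECoG/sEEG). Provides HDF5-backed
    project/subject data storage, notch filtering and per-electrode data
    quality analytics, Morlet wavelet time-frequency decomposition with
    post-wavelet downsampling, common-average/white-matter/bipolar
    re-referencing performed in the complex spectral domain, analog trigger
    event detection and trial epoching, baseline normalization (percent,
    z-score, decibel units), per-electrode condition contrasts with
    Benjamini-Hochberg FDR correction, multi-criteria electrode selection,
    and group-level linear mixed-effects analysis with electrodes nested
    within subjects. A synthetic-data generator with known ground truth
    (1/f background, line noise, trigger pulses, condition-locked
    band-limited power changes, subject- and electrode-level random
    effects) makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    rhdf5,
    signal,
    yaml,
    jsonlite,
    lme4,
    lmerTest,
    emmeans
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'data_store.R'
    'epoching.R'
    'group_analysis.R'
    'ieegpipe-package.R'
    'pipeline.R'
    'power_analysis.R'
    'preprocess.R'
    'referencing.R'
    'selection.R'
    'synthetic_data.R'
    'utils.R'
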