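Package: qeegstroke
Title: Quantitative EEG Stroke-Severity Indices and Classification from
    Portable Headband Recordings
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing short resting-state recordings from
    low-cost portable EEG headbands (four dry electrodes plus on-board
    accelerometer and gyroscope) in the context of acute ischemic stroke
    triage.  Implements Morlet-wavelet spectral power estimation, the
    pairwise-derived brain symmetry index (pdBSI) and its low/high
    frequency and frontal variants, delta/alpha and
    (delta+theta)/(alpha+beta) slowing ratios, a robust fixed-mode
    aperiodic (1/f) spectral fit, per-axis head-motion variability
    statistics, and bootstrap-aggregated classification trees scored by
    out-of-bag confusion matrices.  Includes a synthetic-cohort generator
    that emulates severity-scaled EEG slowing and lesion-lateralised
    spectral asymmetry so that every pipeline stage is testable without
    clinical data, plus session I/O for delimited (MuseLSL-style CSV) and
    EDF formats and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
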