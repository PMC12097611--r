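Package: bcifuse
Title: Multimodal EEG-fTCD Brain-Computer Interface Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multimodal brain-computer interfaces that
    combine electroencephalography (EEG) with functional transcranial Doppler
    ultrasound (fTCD). Implements filter-bank common spatial patterns (FBCSP)
    for EEG trials, maximal-velocity envelope extraction and a time-series
    feature catalogue for raw Doppler trials, Wilcoxon rank-sum feature
    screening, per-modality linear evidence projection, and weighted Bayesian
    probabilistic fusion of the two evidence streams with Gaussian kernel
    density estimates, evaluated under stratified k-fold cross-validation.
    Includes a synthetic paired-data generator with known class structure for
    validation, and a command-line front-end for reproducible runs.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    MASS,
    jsonlite,
    yaml,
    digest
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
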