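Package: eegdem
Title: EEG Spectral Features and Decision-Tree Classification for Dementia Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to classify multichannel resting-state EEG recordings into
    healthy-control, mild-cognitive-impairment and Alzheimer's-disease groups.
    Implements preprocessing of 10-20 montage recordings (central-window
    selection, Fourier-domain resampling to 256 Hz), Fourier band-magnitude
    features, discrete-wavelet-transform features with adaptive
    threshold-based artifact attenuation (sym3 denoising, db4 feature
    extraction), C4.5-style gain-ratio decision trees with human-readable
    rule export, cross-validation and label-permutation validation, and a
    synthetic EEG cohort generator with class-dependent band-power structure
    so the full pipeline can be exercised without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Rcpp,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
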