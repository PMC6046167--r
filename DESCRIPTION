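Package: afcsp
Title: Amplitude-Frequency Common Spatial Patterns for Single-Joint Motor
    Imagery EEG Decoding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Three-class motor imagery decoding for single-joint EEG: trials
    are notch-filtered and common-average referenced, decomposed per channel
    by empirical mode decomposition, and the FFT amplitude spectra of the
    first two intrinsic mode functions over the mu (8-13 Hz) and beta
    (13-30 Hz) bands form an amplitude-frequency matrix per trial. Pairwise
    common spatial pattern filters extract 4-D log-variance features, a
    one-vs-one twin support vector machine (linear or RBF kernel) classifies
    them by hyperplane-distance voting, and NSGA-II tunes the shared penalty
    parameters and kernel width against cross-validated per-class accuracy
    objectives. Includes a synthetic ERD/ERS EEG generator for end-to-end
    testing, confusion-matrix and Cohen's kappa reporting, and a thin
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    kernlab,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
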