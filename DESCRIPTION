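Package: microstatr
Title: Resting-State EEG Microstate Analysis for Case-Control Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements the standard resting-state EEG microstate pipeline:
    zero-phase band-pass filtering, decimation, epoching and amplitude-based
    artifact screening; global field power (GFP) peak extraction;
    polarity-invariant modified K-means clustering of peak topographies into
    the four canonical classes A-D; backfitting with minimum-duration
    smoothing; the Duration, Frequency and Coverage parameters with global
    explained variance; and three-group comparison via Wilks' Lambda MANOVA
    with Bonferroni-controlled post-hoc ANOVAs. Includes a semi-Markov
    synthetic multichannel-EEG generator with full ground truth so the whole
    pipeline is testable by parameter recovery, and minimal EDF read/write.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
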