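Package: bseegtda
Title: Bispectral EEG and Topological Delirium-Screening Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the bispectral EEG (BSEEG) delirium-screening score --
    a log power-spectral-density ratio of slow (3 Hz) to fast (10 Hz)
    forehead-EEG activity -- and its topological enhancement, the TDA score:
    the area of the degree-1 Betti curve of Vietoris-Rips persistent
    homology applied to time-delay embeddings of short EEG windows.
    Includes the full processing pipeline (band-pass filtering, fixed-length
    windowing, artifact rejection, a minimum-usable-signal gate), EDF and
    CSV signal input/output, ROC/AUC evaluation with DeLong confidence
    intervals and paired DeLong comparison of two scores, operating-point
    specificity at fixed sensitivity, and a synthetic EEG generator
    (alpha-dominant normal vs. delta/theta-dominant diffuse slowing, with
    EMG, ECG, drift and flatline artifacts) so every stage is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    pROC,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
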