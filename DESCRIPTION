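Package: tmslandscape
Title: Energy-Landscape Analysis of TMS-Evoked EEG Brain Network States
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for extracting brain connectivity
    signatures from transcranial magnetic stimulation (TMS) evoked EEG.
    Synthetic multi-subject scalp EEG cohorts with known ground truth are
    generated from a toy forward model; epochs are cleaned (amplitude
    rejection, trial averaging, zero-phase FIR bandpass, decimation,
    common-average re-reference), source-localized with a standardized
    minimum-norm (sLORETA) inverse operator, and reduced to alpha-band
    region-of-interest power. Binarized network activity is modelled with a
    pairwise maximum-entropy (Ising) model; the resulting energy landscape
    (local minima, disconnectivity barriers, subject-wise pattern energies)
    feeds paired and two-sample comparisons with per-network Bonferroni
    gating and Cohen's d effect sizes to select group-difference signatures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
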