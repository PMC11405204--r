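Package: seiznet
Title: In Vitro Seizure-Network Analysis for Microelectrode-Array Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for studying hyperexcitability-driven network
    changes in neuronal cultures recorded on microelectrode arrays (MEAs), and
    for phase-synchronization analysis of intracranial EEG. Provides voltage
    conditioning (downsampling, Butterworth band-pass, line-noise notch
    cascade, z-scoring), robust-threshold spike extraction, population-burst
    detection, burst-excluded functional connectivity from 50-ms binned spike
    counts (Fisher-z Pearson correlation), per-well PCA trajectory embedding
    with distance-to-baseline quantification, phase-locking value analysis of
    narrowband signals, and the accompanying statistical toolbox (t-tests,
    D'Agostino-Pearson normality gate, Holm-Bonferroni correction, Cohen's d).
    A synthetic-data generator produces coupled spike-train wells, voltage
    traces and phase-coupled signal pairs with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
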