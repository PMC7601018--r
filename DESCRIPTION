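Package: mccims
Title: Analysis Pipeline for Multi-Capillary-Column Ion-Mobility-Spectrometry
    Breath Data
Version: 0.1.0
Authors@R:
    person("MCC-IMS", "Tools", email = "mccims@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of multi-capillary-column
    ion-mobility-spectrometry (MCC-IMS) measurements in a binary
    case-control setting: intensity normalization against the reactant ion
    peak, quantile baseline correction, noise subtraction, wavelet /
    Gaussian / median / Savitzky-Golay denoising, peak detection (tophat
    morphology, monotone-rise search, falling-water-level watershed,
    annotation rectangles), deterministic probe-clustering grid and DBSCAN
    peak alignment, presence-based feature reduction, Mann-Whitney U +
    Benjamini-Hochberg and random-forest Gini feature scoring, stratified
    cross-validation with dynamic fold selection, decision-tree model
    interpretation, and prediction on held-out samples.  Includes a
    synthetic spectrum generator with planted ground-truth peaks so the
    whole pipeline is testable offline, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
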