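Package: capsheet
Title: Quantification of Calcium-Phosphate Sheet Aggregates in Cryo-EM Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing calcium-phosphate sheet aggregates
    observed in cryo-electron micrographs of primary neuron cultures.
    Implements per-aggregate adaptive-threshold area measurement with
    nonparametric group comparison (Wilcoxon rank-sum with
    Benjamini-Hochberg correction), reduction of low-dose selected-area
    electron diffraction frames to calibrated radial profiles with
    band normalization, background-ratio correction and d-spacing band
    detection in the octacalcium-phosphate diagnostic window, Fisher's
    exact association analysis for aggregate location versus marker
    status, and synthetic phantom generators with exact ground truth so
    the whole pipeline is testable without microscope data. Reads and
    writes MRC and TIFF images and CSV/JSON tables, and ships a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    optparse,
    stats,
    tiff,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
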