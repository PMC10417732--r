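Package: crcdeconv
Title: Multi-Omic Deconvolution of Circulating Rare Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies circulating rare cells from enrichment-free liquid
    biopsy slides into epithelial circulating tumor cells (EPI.CTC),
    partial-EMT CTCs (pEMT.CTC) and circulating endothelial cells (CEC) by
    fusing three evidence layers: immunofluorescence detection via a
    standard-deviations-over-the-mean (SDOM) cytokeratin statistic against
    the surrounding leukocytes, single-cell copy-number profiling (binning,
    GC normalization, circular binary segmentation, gain/loss calling and
    clonality by shared breakpoints), and imaging-mass-cytometry protein
    z-scores anchored to a white-blood-cell reference. Includes a synthetic
    slide/read/ion-count generator with ground-truth labels for end-to-end
    validation, morphometrics (moment-based eccentricity), longitudinal
    per-draw summaries, and Kruskal-Wallis/Dunn group comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    dplyr,
    ggplot2,
    jsonlite,
    optparse,
    pheatmap,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
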