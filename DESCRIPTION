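Package: ramfish
Title: Quantitative Single-Molecule RNA FISH Analysis for Plant Root Meristem Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative single-molecule RNA fluorescence in situ
    hybridization (smFISH) in Arabidopsis root apical meristem cells. Implements
    the widefield quantification chain (maximum z-projection, rolling-ball
    background subtraction by grayscale opening with a spherical-cap element,
    prominence-based local-maxima spot calling, polygonal cell ROI measurement),
    per-cell transcript counting with volume-scaled concentration estimates,
    total corrected cellular fluorescence (TCCF) probe-set comparison with
    one-way ANOVA and Tukey HSD, dual-dye spot co-localization, reference-gene
    probe-set screening (probe tiling, off-target Hamming scan, selection
    criteria), and a synthetic smFISH image and study-table generator with
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    readxl,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
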