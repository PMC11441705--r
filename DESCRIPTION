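Package: centrofate
Title: Single-Cell Lineage Fate, Cell-Cycle, Karyotype and Centrosome-Cohort
    Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying chemotherapy responses of cancer cells at
    single-cell resolution and relating centrosome numbers to clinical outcome.
    Implements lineage, generation and mitosis-to-fate analyses of annotated
    time-lapse movies of dividing cells; FUCCI cell-cycle phase analytics;
    bin-size-weighted aneuploidy and karyotype-heterogeneity scores for
    single-cell copy-number matrices together with the associated library
    curation filters; centrosome-to-nucleus-ratio (CNR) computation with
    depth-one CART dichotomization, Kaplan-Meier curves and log-rank tests;
    and h-maxima based counting of nuclear DNA-damage foci. Seeded synthetic
    generators produce event logs, phase tracks, copy-number matrices,
    cohorts and spot images with known ground truth so that every analysis
    is testable without raw imaging or sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    survival,
    tiff,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    rpart,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
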