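Package: barcodegap
Title: DNA Barcoding Species Discrimination, K2P Divergence and
    Barcoding-Gap Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for distance-based species discrimination with DNA
    barcodes (mitochondrial COI and similar markers): alignment input and
    coding-integrity quality control under the vertebrate mitochondrial
    code, Kimura two-parameter (K2P) pairwise distances with pairwise
    deletion, hierarchical divergence summaries across taxonomic ranks,
    barcoding-gap testing (10x criterion and intra/inter overlap
    detection), gap-scored single-linkage threshold partitioning into
    molecular taxonomic units, neighbour-joining trees with bootstrap
    support and monophyly checks, reference-library identification at a
    percent-identity threshold, morphology-versus-molecular concordance
    classification, and a calibrated coding-sequence simulator for
    end-to-end validation. All user-facing functions take and return
    tidy data frames.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
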