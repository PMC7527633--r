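Package: sweepscan
Title: Selective-Sweep Scans for Two-Population Genotype Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sliding-window detection of selective sweeps from two-population
    diploid genotype data: nucleotide diversity (theta-pi), Watterson's theta,
    and Weir-Cockerham or Hudson F_ST over a sliding-window grid, joint
    top-quantile empirical thresholding, merging of selected windows into
    candidate regions, and gene/feature overlap. Supporting population-structure
    analyses (identity-by-state distances, neighbour-joining trees, genotype
    PCA, linkage-disequilibrium decay and pruning), variant site filtering and
    functional annotation against gene models, and a synthetic two-population
    cohort simulator with planted sweeps so the whole pipeline runs end to end
    without external data. All user-facing functions take and return tidy data
    frames.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    ape,
    S4Vectors,
    vcfR,
    Biostrings,
    IRanges,
    rtracklayer,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    phangorn,
    withr
Config/testthat/edition: 3
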