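Package: sorc
Title: Stability Selection on Random Collapsing for Rare-Variant Ranking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Ranks candidate functional rare variants in quantitative-trait
    association studies by stability selection on random collapsing (SORC).
    Rare variants within each gene are repeatedly split into random subgroups
    and collapsed into carrier indicators; an L1-penalized regression with
    cross-validated regularization selects variants each repetition, and the
    per-variant selection frequency ("stability") across repetitions ranks
    candidates. Includes the standard single-marker, gene-collapsing and
    combined multivariate-and-collapsing (CMC) comparison tests, a
    mini-exome-style cohort simulator with multiple phenotype replicates over
    a fixed genotype matrix, and readers and writers for VCF and tabular
    genotype, gene-map and phenotype files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    optparse,
    readr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
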