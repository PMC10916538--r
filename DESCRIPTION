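Package: secretomics
Title: Single-Cell Secretome Polyfunctionality Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of single-cell cytokine secretion profiles from
    antibody-barcoded 32-plex assays of T cells. Computes polyfunctional
    strength indices (PSI) over predefined cytokine functional groups,
    runs pseudobulk contrasts across tissue, timepoint and therapy
    response, embeds and clusters cells from mean-fluorescence-intensity
    profiles (log normalization, PCA, patient-level batch correction,
    kNN graph, Leiden communities, UMAP), tests kNN-neighborhood
    differential abundance between timepoints with a spatially weighted
    false discovery rate, and derives de novo polyfunctional groups by
    hierarchical clustering of cluster-level cytokine signatures. Ships
    a zero-inflated log-normal cohort simulator so every stage is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    MASS,
    purrr,
    RANN,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    uwot,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
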