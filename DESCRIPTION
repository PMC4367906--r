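Package: mitoscreen
Title: Analysis of Image-Based Kinome RNAi Screens for Mitotic Index Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for high-content RNAi screens that read out
    the mitotic index (phospho-histone H3 positive cells over DAPI-stained
    nuclei). Covers simplified fluorescence image quantification
    (illumination correction, thresholding, object counting), quality-control
    filtering, plate-median normalization, robust MAD-based hit calling into
    low- and high-mitotic-index kinase groups, hypergeometric and Fisher
    term-enrichment statistics, and construction and topological analysis of
    typed kinase-substrate interaction networks. A synthetic-data module
    generates plate-based screens, fluorescence image pairs, scale-free typed
    interactomes and annotation tables with recorded ground truth for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    igraph,
    EBImage,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
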