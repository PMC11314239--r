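Package: dusrank
Title: Diversity, Breeding Trends and TOPSIS Ranking of DUS-Coded Germplasm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for coded DUS (Distinctness, Uniformity,
    Stability) phenotype characteristics of germplasm collections:
    per-characteristic descriptive statistics and Shannon diversity,
    a 10-grade coding transform for measured traits, pairwise Pearson
    correlation with significance tiers, correlation-matrix PCA with
    Kaiser component selection, Ward hierarchical clustering of
    varieties, landrace-versus-cultivated differential analysis of
    breeding trends, and a trend-directed TOPSIS multi-criteria
    decision model that ranks varieties by breeding potential. Includes
    a seeded synthetic-cohort generator that emulates the marginal
    structure of a foxtail millet DUS study so every pipeline stage is
    testable without unpublished raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
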