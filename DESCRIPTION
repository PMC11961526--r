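Package: osteorda
Title: Osteometric Size-Shape Decomposition and Regularized Discriminant
    Classification for Reindeer Bone Assemblages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the multivariate osteometric separation of reindeer
    (Rangifer tarandus) ecotypes, varieties, sexes, and castrates from
    long-bone and pelvis measurements. Provides a standard measurement
    registry with bone-region tags, readers and inclusion filters for wide
    measurement tables, Mennerich slenderness indices, the Mosimann
    isometric-size / log-shape-ratio decomposition, a from-scratch
    regularized discriminant analysis (Friedman-style lambda/gamma
    covariance shrinkage) with stratified train/test splitting and
    cross-validated tuning, classification experiments over bone-region
    variable subsets emulating fragmentary finds, and a seeded synthetic
    assemblage generator with the dimorphism and castration structure the
    analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    purrr,
    readr,
    readxl,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    mvtnorm,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
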