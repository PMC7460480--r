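Package: mdagwas
Title: Multivariate Discriminant Genome-Wide Association Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Genome-wide association mapping by multivariate discriminant
    analysis for two-group (low/high phenotype) designs. Implements
    per-chromosome canonical discriminant analysis with coefficient-based
    marker screening, stepwise discriminant reduction on Wilks' lambda,
    Mahalanobis/Hotelling separation tests, centroid-cutoff discriminant
    classification, and recursive pruning to the minimal marker set that
    still separates the groups.  Ships a forward-in-time livestock
    population simulator (historical drift-mutation phase plus pedigreed
    recent generations with QTL, polygenic and residual trait components),
    PLINK text/binary genotype input and output, mixed-model phenotype
    pre-adjustment with a genomic relationship matrix, a single-marker
    regression comparator with principal-component correction and
    Benjamini-Hochberg false discovery rate control, and a QTL-detection
    evaluation harness for scaled simulation experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
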