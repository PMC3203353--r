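Package: vishotspot
Title: Viral Integration Site Hot-Spot Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects genomic hot-spots of viral vector integration sites (VIS)
    for gene-therapy safety analysis. Implements three hot-spot definitions:
    the conventional common insertion site (CIS) sliding-window density rule,
    a z-threshold method that standardises VIS counts over 1 Mb genome bins
    and thresholds the z-scores, and a Bayesian change-point (BCP) method that
    fits a product-partition Gaussian model to the bin z-scores by Gibbs
    sampling and thresholds the posterior bin means. Also provides dataset
    clustering metrics, Fisher exact tests of hot-bin conservation between
    datasets, genomic-feature density analysis of hot-spots, a subsampling
    study of hot-spot size-invariance, shifted-partition merging, a synthetic
    VIS generator, and genome/chromosome visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
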