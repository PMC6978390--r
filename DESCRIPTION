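Package: regplexus
Title: Promoter-Anchored Regulatory Plexus Inference from Chromatin
    Accessibility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers the regulatory plexus of a gene promoter from
    cross-cell-type chromatin accessibility correlation within a
    topologically associating domain (TAD), annotates candidate
    cis-regulatory elements (CREs) with chromatin tracks, intersects them
    with somatic single-nucleotide variants, and reports the resulting
    filter cascade. Also provides a permutation median test for group
    gene essentiality, percentile ranking, and the normalization and
    hypothesis-test statistics used to score perturbation, reporter and
    allele-specific experiments. A synthetic-data generator plants known
    ground truth so the full pipeline is testable without external
    downloads.
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
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
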