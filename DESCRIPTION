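Package: stagemapr
Title: Comparative Single-Cell RNA-Seq Analysis of Paired Developmental Stages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for comparative single-cell RNA-seq analysis of
    differentiation across two developmental stages, built around plate-based
    (CEL-Seq2 layout) UMI data. Provides UMI quantification with binomial
    collision correction and gene-locus merging, a cell and gene quality-control
    cascade with downscaling normalization, medoid-based clustering with a
    negative-binomial background noise model and probability-threshold outlier
    detection, an exact conditional negative-binomial test for differential
    expression, quadratic-programming projection of query cells onto reference
    cluster medoids under simplex constraints, lineage-link inference with
    pseudo-temporal ordering and self-organizing-map gene modules, and
    random-forest gene regulatory network edge ranking. A seeded synthetic-data
    generator produces paired-stage datasets with full ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
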