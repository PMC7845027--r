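Package: refstab
Title: Reference-Gene Discovery and Validation for RT-qPCR Normalization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Screens stable, abundant candidate reference genes from
    multi-experiment RNA-seq expression compendia, scores candidates with
    four expression-stability statistics (geNorm M, NormFinder model-based
    stability, BestKeeper descriptive statistics, and the pairwise delta-Ct
    method), merges the per-method rankings by cross-entropy Monte-Carlo
    rank aggregation, determines the optimal number of reference genes from
    the geNorm pairwise-variation series, and validates reference-gene
    choices by delta-delta-Cq relative quantification and Pearson
    concordance of normalization schemes. Includes a synthetic-data
    generator that plants stability structure into FPKM compendia and
    replicated Cq tables so the whole workflow is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
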