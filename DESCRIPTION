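Package: scexoclone
Title: Single-Cell Exome Somatic Mutation Calling and Clonal Architecture
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Error-model estimation, somatic mutation calling and clonal
    reconstruction for single-cell whole-exome sequencing of a tumor and its
    matched normal tissue. Estimates allele dropout (ADO) and per-site false
    discovery rates from single normal cells, derives binomial cell-count
    thresholds for somatic calling, calls somatic point mutations across a
    cell population, builds the somatic mutant allele frequency spectrum
    (SMAFS) with hyperbolic-decay goodness-of-fit and selection tests, and
    reconstructs tumor subclones from Bayesian genotype-posterior log-odds
    via two-dimensional hierarchical clustering. Includes a synthetic-data
    generator that emulates a clonally structured tumor cell population
    observed through allele dropout, false positives and variable coverage,
    with ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    cluster,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    ape
Config/testthat/edition: 3
RoxygenNote: 7.3.3
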