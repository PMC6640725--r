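Package: regulatome
Title: Cell-Death Regulatome Screening and Chromatin Long-Range
    Interaction Distance Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for screening the expression of a curated 299-gene
    cell-death "regulatome" spanning 13 cell-death modalities in two-group
    microarray comparisons. Ingests signed fold-change tables or raw
    two-group expression matrices, runs a housekeeping-gene quality check,
    applies a strict 1.5-fold up/down classifier annotated by cell-death
    type and auxiliary gene panels (housekeeping, redox, chromatin
    conformation factors), and computes cross-condition overlaps of the
    resulting calls. A companion component anchors chromatin long-range
    interaction sites to gene promoters, computes signed upstream and
    downstream distances, summarises their distributions, and compares
    gene sets with a two-sample Kolmogorov-Smirnov test (asymptotic and
    exact permutation p-values). Synthetic-data generators with known
    ground truth make every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
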