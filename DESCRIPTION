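Package: constraintdepth
Title: Constraint-Depth Analysis of Multispecies Genome Alignments
Version: 0.1.0
Authors@R: person("Constraintdepth", "Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A desk-scale pipeline for measuring evolutionary sequence
    constraint in reference-anchored multispecies alignments and assigning
    each genomic element a depth of constraint. Provides a reversible
    nucleotide substitution model with Felsenstein pruning, EM fitting of a
    neutral background model from designated neutral columns, likelihood-ratio
    constraint/acceleration scores for single bases and whole elements
    (phyloP-style, with a free subtree rate-scale factor), a two-state
    phylo-HMM segmentation into conserved elements (phastCons-style), Storey
    q-value multiple-testing control and clade-exclusivity depth
    classification, an ultraconserved-element scanner, downstream enrichment
    statistics (fine-mapped variant enrichment, length-binned motif odds-ratio
    meta-analysis, reporter-assay correlation, assembly mismatch regression),
    and a seeded synthetic-data generator that plants constrained elements so
    every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
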