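Package: pairseq
Title: Paired Single-Cell and Single-Nucleus RNA-Seq Comparison Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to compare the biology recovered by single-cell and
    single-nucleus RNA sequencing of patient-matched normal and tumor tissue
    samples. Implements MAD-based per-sample quality control with a capped
    mitochondrial rule, artificial-nearest-neighbour doublet detection,
    hierarchical reference-based cell-type annotation with confidence scores,
    expression-based copy-number inference with a quintile malignancy rule,
    pseudobulk negative-binomial differential expression with a
    concordance null expectation, a permutation-tested ligand-receptor
    interactome, and composition, silhouette, stress-signature and
    mitochondrial-fraction comparison metrics. A synthetic paired-cohort
    generator with known ground truth exercises every stage end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    MASS,
    methods,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    cluster,
    car,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape
Config/testthat/edition: 3
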