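Package: mosaicscan
Title: Single-Cell Inference of Chromosomal Mosaicism in Human Embryos
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end inference of chromosomal mosaicism from single-cell
    data of pre- and post-implantation human embryos. Provides per-cell
    copy-number calling from low-pass whole-genome binned read counts with
    GC/mappability correction, a variability-score quality filter, density
    based calibration of gain/loss log2-ratio cutoffs and a three-state
    hidden-Markov segmentation; embryo-level classification of meiotic
    versus mitotic aneuploidy, detection of complementary (reciprocal
    gain/loss) cells with a permutation null, and lineage reconstruction
    from shared aberrations; an expression plus allelic-imbalance
    aneuploidy caller for single-cell RNA-seq with DNA-truth validation;
    a mosaic-fraction estimator for pooled multicell biopsies; and a
    synthetic-data generator that emulates all of these inputs coupled to
    ground truth so the whole pipeline is testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mclust,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    Matrix,
    ape,
    knitr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
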