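Package: draftqc
Title: Draft Genome Quality Control, LTR Insertion Dating and Expression Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative toolkit for draft plant genome projects: k-mer
    spectrum genome-size estimation from shotgun reads, Chargaff
    second-parity (reverse-complement k-mer symmetry) assembly QC,
    LTR-retrotransposon insertion-age dating via Kimura two-parameter
    distances between the two long terminal repeats (T = K/(2r)),
    GC-composition and gene-structure profiling from GFF3 gene models, and
    housekeeping-gene (EF1A) normalized cross-species expression
    comparison. Includes seedable synthetic-data generators (bimodal-GC
    genomes, planted LTR elements evolved under an exact K2P process,
    gene models, uniform-coverage reads, log-normal FPKM tables) so every
    stage is validated against planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    Rcpp,
    S4Vectors,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
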