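Package: regconverge
Title: Cross-Lineage Regulatory Convergence Analysis for Single-Cell Multi-Omics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies convergence of distinct embryonic lineages onto a shared
    chondrogenic regulatory state from paired single-cell RNA and ATAC count data.
    Provides pseudobulk Spearman co-clustering of transcriptomes, logistic-regression
    marker testing with latent covariates, summit-centred fixed-width peak
    finalisation with iterative overlap removal, genomic categorisation and
    promoter-versus-distal cross-lineage similarity, pseudotime binning with
    cross-lineage trajectory alignment by open-ended dynamic time warping,
    position weight matrix trimming/similarity/deduplication and per-cell motif
    deviation scoring with matched background peak sets, aggregate-based
    peak-to-gene link discovery with hkmeans clustering and conservation
    summaries, and a synthetic three-lineage multi-omic cohort generator with
    planted ground truth for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
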