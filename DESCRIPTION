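Package: sdmt
Title: Spatial Co-Profiling of DNA Methylation and Transcriptome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Toolkit for spatially barcoded, enzymatically deaminated
    co-profiling of DNA methylation and gene expression on a combinatorial
    barcode pixel grid. Covers deamination-tolerant barcode demultiplexing,
    per-pixel methylation calling and quality control (retention rates,
    conversion efficiency on methylation-free linkers, knee-plot pixel
    filtering), detection of variably methylated regions with shrunken
    residuals, iterative-PCA imputation of sparse methylation matrices,
    weighted-nearest-neighbour fusion of the methylation and RNA modalities
    with graph clustering, and downstream statistics (rank-sum differential
    features, methylation-expression correlation, CpG-set fold enrichment).
    Includes a synthetic-data generator with ground truth so that every
    stage is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    methods,
    Matrix,
    data.table,
    igraph,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
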