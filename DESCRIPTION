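Package: scnome
Title: Single-Cell NOMe-Seq Processing: Demultiplexing, Methylation,
    Accessibility and Epigenetic Clocks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing pipeline for split-pool combinatorially barcoded
    single-cell bisulfite (NOMe-seq style) data. Parses fixed-layout reads,
    corrects ligation barcodes against whitelists by Levenshtein distance,
    deduplicates aligned records, classifies cytosine contexts (WCG/GCH/WCH),
    tabulates per-cell methylation and QC statistics, calls nucleosome-depleted
    regions from pseudo-bulk GpC methylation by sliding-window chi-square
    testing, builds cell-by-bin methylation matrices with filtering, imputation,
    PCA/Leiden/UMAP embedding, infers coarse copy-number profiles from read
    depth in fixed windows, and estimates single-cell epigenetic age by
    profile likelihood over binarized CpG calls together with a mitotic-clock
    score. Ships a seeded synthetic-data generator so the whole pipeline is
    testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    uwot
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
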