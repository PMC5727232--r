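Package: SBEscan
Title: Motif Scanning and Cluster Enrichment of GC-Rich Smad Binding Elements
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Strand-aware IUPAC scanning of Smad binding elements (the
    GC-rich 5GC panel GGCGC/GGCGG/GGCCG/GGCTG, CAGAC, AGAC and the
    context-restricted DAGAC) in DNA sequence, construction of
    peak-centered promoter-proximal analysis windows from ChIP-Seq peaks
    and TSS annotation, random genomic baseline sampling, per-region
    motif profiles, fold-enrichment and cluster statistics, a
    footprint-capacity model for MH1 domain occupancy, an EMSA
    probe-tiling designer, and a fully synthetic data generator with
    planted ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    withr,
    jsonlite,
    yaml,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    Rsamtools,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
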