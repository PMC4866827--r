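Package: L1atlas
Title: Mapping and Expression Analysis of L1HS-Ta Retrotransposon Insertions
    from ATLAS-seq Junction Reads
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements the computational pipeline for locating young LINE-1
    (L1HS-Ta) retrotransposon insertions from ATLAS-seq targeted junction
    sequencing: error-tolerant read-grammar trimming, linker-position
    deduplication, strand-aware clustering, insertion-point calling, 5'/3'
    pairing into full-length elements, annotation against reference and
    polymorphism catalogs, support/primer-artifact/PreTa filtering, split-read
    3' transduction detection and lineage-tag tracing. Also provides
    locus-resolution L1 expression analysis from stranded RNA-seq
    (1-kb flanking-window FPKM, expressed/absent classification, diagnostic
    trinucleotide subfamily counting, flank metaprofiles and two bespoke
    clusterings) and a fully deterministic synthetic-data generator with
    ground truth for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    SummarizedExperiment,
    jsonlite,
    ape
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Sequencing, Transcriptomics, Coverage, Alignment, Software
RoxygenNote: 7.3.3
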