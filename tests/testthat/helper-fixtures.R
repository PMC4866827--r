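# Small constructors shared across test files.

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(S4Vectors)
})

# alignment GRanges in the package's expected shape
mk_aln <- function(chrom, start, end, strand, read_id = NULL, mapq = 60L,
                   is_secondary = FALSE, n_dup = NULL,
                   polyA = FALSE, l1_end = FALSE, primer = FALSE,
                   clip = NULL, seqlen = NULL) {
    n <- max(length(start), length(end))
    if (is.null(read_id)) read_id <- sprintf("r%03d", seq_len(n))
    gr <- GRanges(chrom, IRanges(start, end), strand = strand)
    if (!is.null(seqlen))
        GenomeInfoDb::seqlengths(gr) <- seqlen
    mcols(gr) <- DataFrame(
        read_id = read_id,
        mapq = rep(as.integer(mapq), length.out = n),
        is_secondary = rep(is_secondary, length.out = n),
        polyA = rep(polyA, length.out = n),
        l1_end = rep(l1_end, length.out = n),
        primer = rep(primer, length.out = n))
    if (!is.null(n_dup)) mcols(gr)$n_dup <- as.integer(n_dup)
    if (!is.null(clip)) {
        mcols(gr)$clip_chrom <- clip$chrom
        mcols(gr)$clip_start <- clip$start
        mcols(gr)$clip_end <- clip$end
        mcols(gr)$clip_strand <- clip$strand
        mcols(gr)$clip_mapq <- clip$mapq
    } else {
        mcols(gr)$clip_chrom <- NA_character_
        mcols(gr)$clip_start <- NA_integer_
        mcols(gr)$clip_end <- NA_integer_
        mcols(gr)$clip_strand <- NA_character_
        mcols(gr)$clip_mapq <- NA_integer_
    }
    gr
}

# minimal 3' call GRanges with the bookkeeping columns the filters expect
mk_call <- function(chrom, point, orientation, n_nonredundant = 3L,
                    n_polyA_or_l1 = 1L, n_primer_only = 0L,
                    n_nonredundant_5p = 0L, cluster_start = point - 200L,
                    cluster_end = point, is_reference = FALSE,
                    full_length = FALSE, call_id = NULL) {
    n <- length(point)
    if (is.null(call_id)) call_id <- sprintf("call%02d", seq_len(n))
    gr <- GRanges(chrom, IRanges(point, width = 1L),
                  strand = orientation)
    mcols(gr) <- DataFrame(
        call_id = call_id, side = "three_prime",
        cluster_start = rep(as.integer(cluster_start), length.out = n),
        cluster_end = rep(as.integer(cluster_end), length.out = n),
        cluster_strand = ifelse(orientation == "+", "-", "+"),
        n_nonredundant = rep(as.integer(n_nonredundant), length.out = n),
        n_redundant = rep(as.integer(n_nonredundant), length.out = n),
        n_polyA_or_l1 = rep(as.integer(n_polyA_or_l1), length.out = n),
        n_primer_only = rep(as.integer(n_primer_only), length.out = n),
        full_length = rep(full_length, length.out = n),
        pair_distance = rep(NA_integer_, n),
        n_nonredundant_5p = rep(as.integer(n_nonredundant_5p),
                                length.out = n),
        is_reference = rep(is_reference, length.out = n))
    gr
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

mutate_subs <- function(seq, pos) {
    ch <- strsplit(seq, "")[[1]]
    for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
    paste(ch, collapse = "")
}

# a tiny simulated experiment reused by several files (cached)
small_sim <- local({
    cache <- NULL
    function() {
        if (is.null(cache))
            cache <<- simulateAtlasExperiment(simulationParams(
                n_insertions = 10L, genome_len = 260000L,
                n_primer_decoys = 3L, n_preta = 2L,
                n_transduction_pairs = 1L, n_lineage_insertions = 0L,
                substitution_rate = 0, duplicate_rate = 0.3, seed = 11L))
        cache
    }
})
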