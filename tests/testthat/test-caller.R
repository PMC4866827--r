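test_that("alignment filtering removes secondary and MAPQ<=20 records", {
    gr <- mk_aln("chr1", c(100, 200, 300), c(180, 280, 380), "+",
                 mapq = c(20L, 21L, 60L),
                 is_secondary = c(FALSE, FALSE, TRUE))
    out <- filterAlignments(gr, 20)
    expect_equal(mcols(out)$read_id, "r002")  # MAPQ 21 primary survives
})

test_that("deduplication keeps the longest read per linker position with deterministic ties", {
    gr <- mk_aln("chr1", c(121, 101, 101, 131, 111),
                 c(200, 200, 200, 200, 200), "-",
                 read_id = c("b", "a", "c", "d", "e"))
    # linker position of minus-strand reads is the right end: all share 200
    out <- deduplicateReads(gr)
    expect_equal(length(out), 1L)
    expect_equal(mcols(out)$n_dup, 5L)
    # lengths: a and c tie at the maximum; smallest id wins
    expect_equal(mcols(out)$read_id, "a")
    # distinct linker positions stay distinct
    gr2 <- mk_aln("chr1", c(100, 100), c(200, 201), "+")
    expect_equal(length(deduplicateReads(gr2)), 1L)  # same start on +
    gr3 <- mk_aln("chr1", c(100, 101), c(200, 200), "+")
    expect_equal(length(deduplicateReads(gr3)), 2L)
    # non-redundant count never exceeds redundant count
    expect_true(all(mcols(deduplicateReads(gr))$n_dup >= 1L))
})

test_that("clustering follows bedtools merge semantics at the 100-bp boundary", {
    # 0-based [100,200) and [250,350) -> 1-based [101,200], [251,350]
    gr <- sort(mk_aln("chr1", c(101, 251), c(200, 350), "-"))
    cl <- clusterReads(gr, "three_prime", gap = 100)
    expect_equal(length(cl), 1L)
    expect_equal(c(start(cl), end(cl)), c(101L, 350L))
    # separation of exactly 101 does not merge
    gr2 <- sort(mk_aln("chr1", c(101, 302), c(200, 400), "-"))
    expect_equal(length(clusterReads(gr2, "three_prime", 100)), 2L)
    gr2b <- sort(mk_aln("chr1", c(101, 301), c(200, 400), "-"))
    expect_equal(length(clusterReads(gr2b, "three_prime", 100)), 1L)
    # opposite strands never merge
    gr3 <- sort(mk_aln("chr1", c(101, 120), c(200, 220), c("+", "-")))
    expect_equal(length(clusterReads(gr3, "three_prime", 100)), 2L)
    # unsorted input is an error
    expect_error(clusterReads(mk_aln("chr1", c(500, 100),
                                     c(600, 200), "+"),
                              "three_prime", 100), "sorted")
})

test_that("clustering matches a brute-force transitive-closure oracle", {
    set.seed(202)
    for (case in 1:8) {
        n <- sample(c(20, 80, 200), 1)
        start <- sample(1:5000, n, replace = TRUE)
        width <- sample(20:150, n, replace = TRUE)
        strand <- sample(c("+", "-"), n, replace = TRUE)
        chrom <- sample(c("c1", "c2"), n, replace = TRUE)
        gr <- sort(mk_aln(chrom, start, start + width - 1L, strand),
                   ignore.strand = TRUE)
        cl <- clusterReads(gr, "three_prime", gap = 100)
        want <- oracle_cluster(
            data.frame(chrom = as.character(seqnames(gr)),
                       start = start(gr), end = end(gr),
                       strand = as.character(strand(gr)),
                       stringsAsFactors = FALSE), 100L)
        got <- data.frame(chrom = as.character(seqnames(cl)),
                          start = start(cl), end = end(cl),
                          strand = as.character(strand(cl)),
                          n = mcols(cl)$n_nonredundant,
                          stringsAsFactors = FALSE)
        got <- got[order(got$chrom, got$start, got$strand), ]
        rownames(got) <- NULL
        expect_equal(got, want)
    }
})

test_that("insertion point and orientation derive from cluster strand and side", {
    # 0-based span [1000,1400) = 1-based [1001,1400]
    mk_cl <- function(strand, side) {
        gr <- sort(mk_aln("chr1", c(1001, 1101), c(1200, 1400), strand))
        clusterReads(gr, side, 100)
    }
    sense3 <- callInsertionPoints(mk_cl("-", "three_prime"))
    expect_equal(start(sense3), 1001L)
    expect_equal(as.character(strand(sense3)), "+")
    anti3 <- callInsertionPoints(mk_cl("+", "three_prime"))
    expect_equal(start(anti3), 1400L)
    expect_equal(as.character(strand(anti3)), "-")
    sense5 <- callInsertionPoints(mk_cl("+", "five_prime"))
    expect_equal(start(sense5), 1400L)
    expect_equal(as.character(strand(sense5)), "+")
    anti5 <- callInsertionPoints(mk_cl("-", "five_prime"))
    expect_equal(start(anti5), 1001L)
    expect_equal(as.character(strand(anti5)), "-")
})

test_that("5'/3' pairing respects the 7-kb window, orientation and one-to-one rule", {
    call3 <- callInsertionPoints(clusterReads(
        sort(mk_aln("chr1", 20001, 20200, "-")), "three_prime", 100))
    mk5 <- function(p5end) clusterReads(
        sort(mk_aln("chr1", p5end - 150L, p5end, "+")), "five_prime", 100)
    # 5' junction 6000 bp upstream (element body spans the gap)
    paired <- pairFullLength(call3, mk5(start(call3) - 6001L), 7000)
    expect_true(mcols(paired)$full_length)
    expect_equal(mcols(paired)$pair_distance, 6000L)
    # beyond the window
    far <- pairFullLength(call3, mk5(start(call3) - 8001L), 7000)
    expect_false(mcols(far)$full_length)
    expect_true(is.na(mcols(far)$pair_distance))
    # adjacent junctions (non-reference insertion): distance 0
    near <- pairFullLength(call3, mk5(start(call3) - 1L), 7000)
    expect_true(mcols(near)$full_length)
    expect_equal(mcols(near)$pair_distance, 0L)
    # wrong orientation is never paired
    wrong <- pairFullLength(call3, clusterReads(
        sort(mk_aln("chr1", start(call3) - 6001L - 150L,
                    start(call3) - 6001L, "-")), "five_prime", 100), 7000)
    expect_false(mcols(wrong)$full_length)
    # one 5' cluster cannot support two 3' calls; the nearest wins
    calls2 <- callInsertionPoints(clusterReads(sort(
        mk_aln("chr1", c(20001, 21001), c(20200, 21200), "-")),
        "three_prime", 100))
    paired2 <- pairFullLength(calls2, mk5(20000L), 7000)
    expect_equal(mcols(paired2)$full_length, c(TRUE, FALSE))
})

test_that("annotation assigns known status, gene context and CNV state", {
    calls <- mk_call("chr1", c(1000L, 5000L, 9000L), "+")
    catalogs <- list(
        reference_l1 = GRanges("chr1", IRanges(850, width = 1)),
        known_polymorphic = GRanges("chr1", IRanges(5300, width = 1)),
        genes = GRanges("chr1", IRanges(8000, 12000), strand = "-"),
        cnv = GRanges("chr1", IRanges(1, 6000), state = "amplified"))
    out <- annotateCalls(calls, catalogs, window = 200)
    expect_equal(mcols(out)$known_status,
                 c("reference", "novel", "novel"))  # 5300 is 300 bp away
    ctg2 <- catalogs
    ctg2$known_polymorphic <- GRanges("chr1", IRanges(5150, width = 1))
    out2 <- annotateCalls(calls, ctg2, window = 200)
    expect_equal(mcols(out2)$known_status[2], "known_polymorphic")
    expect_equal(mcols(out)$gene_context,
                 c("intergenic", "intergenic", "genic_antisense"))
    expect_equal(mcols(out)$cnv_state,
                 c("amplified", "amplified", "unknown"))
})

test_that("per-million normalization is exact arithmetic", {
    cl <- clusterReads(sort(mk_aln("chr1", 101, 200, "-", n_dup = 10L)),
                       "three_prime", 100)
    out <- normalizeCounts(cl, 1e6, 2e6)
    expect_equal(mcols(out)$rpm, 10)
    expect_equal(mcols(out)$tpm, 0.5)
    cl3 <- clusterReads(sort(mk_aln("chr1", c(101, 151, 401),
                                    c(200, 250, 500), "-")),
                        "three_prime", 100)
    out3 <- normalizeCounts(cl3, 10, 2e6)
    expect_equal(mcols(out3)$tpm, c(1.0, 0.5))
    expect_lte(sum(mcols(out3)$rpm), 1e6)
    expect_error(normalizeCounts(cl, 0, 1), "positive")
})

test_that("calling is invariant to input read order", {
    sim <- small_sim()
    res <- runAtlasPipeline(sim, tags = NULL)
    sim2 <- sim
    set.seed(1)
    perm <- sample(nrow(sim2$reads_3p))
    sim2$reads_3p <- sim2$reads_3p[perm, ]
    sim2$alignments <- sim2$alignments[sample(length(sim2$alignments))]
    res2 <- runAtlasPipeline(sim2, tags = NULL)
    expect_identical(mcols(res$calls)$call_id, mcols(res2$calls)$call_id)
    expect_identical(start(res$calls), start(res2$calls))
    expect_identical(mcols(res$calls)$retained, mcols(res2$calls)$retained)
})
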