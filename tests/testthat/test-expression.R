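mk_le <- function(sense, antisense = sense * 0, present = NULL) {
    LocusExpression(sense, antisense, present)
}

test_that("flanking-window FPKM counts the right fragments", {
    # full-length sense (+) call: 3' junction at 10000, element length 6000
    call <- mk_call("chr1", 10000L, "+", full_length = TRUE)
    mcols(call)$pair_distance <- 6000L
    frags <- GRanges("chr1",
                     IRanges(c(10100, 10500, 10900, 10950, 11500, 10200,
                               3500, 3600),
                             width = 100),
                     strand = c("+", "+", "+", "+", "+", "-", "-", "-"),
                     mapq = c(60L, 60L, 19L, 60L, 60L, 60L, 60L, 60L))
    q <- quantifyLoci(frags, call, exons = NULL,
                      total_first_mates = 2e6)
    # sense window [10000,10999] on "+": fragments at 10100/10500/10950
    # count; 10900 fails MAPQ, 11500 is outside, 10200 is the wrong strand
    expect_equal(q$sense_fpkm, 3 / 2)
    # antisense window [3000,3999] on "-": 5' ends at 3599 and 3699 count
    expect_equal(q$antisense_fpkm, 2 / 2)
    # no fragments -> 0
    empty <- quantifyLoci(GRanges(), call, total_first_mates = 1e6)
    expect_equal(empty$sense_fpkm, 0)
    # 7 qualifying fragments over 2e6 first mates -> FPKM 3.5
    frags7 <- GRanges("chr1", IRanges(10000 + seq(0, 900, 150),
                                      width = 50),
                      strand = "+", mapq = 60L)
    expect_equal(quantifyLoci(frags7, call,
                              total_first_mates = 2e6)$sense_fpkm, 3.5)
    # exon masking removes overlapping fragments without rescaling
    exons <- GRanges("chr1", IRanges(10450, 10600))
    qm <- quantifyLoci(frags, call, exons = exons,
                       total_first_mates = 2e6)
    expect_equal(qm$sense_fpkm, 2 / 2)
    expect_error(quantifyLoci(frags, call, total_first_mates = 0),
                 "positive")
})

test_that("FPKM is equivariant under library scaling and strand flips move signal", {
    call <- mk_call("chr1", 10000L, "+", full_length = TRUE)
    mcols(call)$pair_distance <- 0L
    frags <- GRanges("chr1", IRanges(c(10100, 10300, 9900), width = 80),
                     strand = c("+", "+", "-"), mapq = 60L)
    q1 <- quantifyLoci(frags, call, total_first_mates = 1e6)
    q2 <- quantifyLoci(rep(frags, 2), call, total_first_mates = 2e6)
    expect_equal(q1$sense_fpkm, q2$sense_fpkm)
    expect_equal(q1$antisense_fpkm, q2$antisense_fpkm)
    # flipping the planted orientation mirrors the windows and strands
    flipped <- mk_call("chr1", 10000L, "-", full_length = TRUE)
    mcols(flipped)$pair_distance <- 0L
    fr2 <- GRanges("chr1", IRanges(c(9400, 9700), width = 80),
                   strand = "-", mapq = 60L)
    expect_equal(quantifyLoci(fr2, call,
                              total_first_mates = 1e6)$sense_fpkm, 0)
    expect_gt(quantifyLoci(fr2, flipped,
                           total_first_mates = 1e6)$sense_fpkm, 0)
})

test_that("expressed classification treats 0.05 as non-expressed and absent as neither", {
    sense <- matrix(c(0.05, 0.051, 0.2, 0.0), 4, 1,
                    dimnames = list(paste0("L", 1:4), "A"))
    present <- matrix(c(TRUE, TRUE, FALSE, TRUE), 4, 1,
                      dimnames = dimnames(sense))
    le <- mk_le(sense, present = present)
    ex <- isExpressed(le)
    expect_identical(as.vector(ex), c(FALSE, TRUE, NA, FALSE))
    # absent loci carry the NA sentinel, not 0
    expect_true(is.na(senseFPKM(le)[3, 1]))
    le2 <- classifyExpressed(le, threshold = 0.05)
    expect_identical(SummarizedExperiment::assay(le2, "expressed"),
                     ex)
    # constructing with numbers at absent loci is rejected downstream
    expect_error(validObject(
        new("LocusExpression",
            SummarizedExperiment::SummarizedExperiment(
                assays = list(sense_fpkm = sense,
                              antisense_fpkm = sense,
                              present = present)))),
        "absent")
})

test_that("diagnostic trinucleotide counting requires a full span", {
    cons <- syntheticL1Consensus()
    mk_read <- function(start, tri = NULL, len = 75) {
        s <- substr(cons, start, start + len - 1)
        if (!is.null(tri)) substr(s, 5927 - start + 1,
                                  5927 - start + 3) <- tri
        data.frame(start = start, seq = s, stringsAsFactors = FALSE)
    }
    alns <- rbind(mk_read(5900, "ACA"), mk_read(5910, "ACA"),
                  mk_read(5880, "ACG"), mk_read(5920, "GAG"),
                  mk_read(5925, "TTT"),
                  mk_read(5928 - 74),   # ends at 5928: partial span
                  mk_read(100))         # far away
    sc <- countDiagnosticTrinucleotides(alns, 5927:5929, 1e7)
    expect_equal(unname(sc$counts["ACA"]), 2L)
    expect_equal(unname(sc$counts["ACG"]), 1L)
    expect_equal(unname(sc$counts["GAG"]), 1L)
    expect_equal(unname(sc$counts["other"]), 1L)
    expect_equal(sc$partial, 1L)
    # 50 ACA reads over 1e7 genome-mapped reads -> 5 per million
    many <- do.call(rbind, replicate(50, mk_read(5900, "ACA"),
                                     simplify = FALSE))
    expect_equal(unname(countDiagnosticTrinucleotides(
        many, 5927:5929, 1e7)$per_million["ACA"]), 5)
})

test_that("simulated consensus reads recover planted subfamily proportions", {
    alns <- simulateConsensusReads(400, c(ACA = 0.1, GAG = 0.9),
                                   n_offsite = 60, seed = 12)
    sc <- countDiagnosticTrinucleotides(alns, 5927:5929, 1e6)
    planted <- table(attr(alns, "planted"))
    expect_equal(unname(sc$counts["ACA"]), unname(planted["ACA"]))
    expect_equal(unname(sc$counts["GAG"]), unname(planted["GAG"]))
    # planted 1:9 ratio recovered within binomial error
    expect_lt(abs(sc$counts["ACA"] / sc$counts["GAG"] - 1 / 9), 0.06)
})

test_that("half-total contributor count matches exhaustive enumeration", {
    expect_equal(halfTotalContributors(c(4, 3, 2, 1)), 2L)
    expect_equal(halfTotalContributors(rep(1, 10)), 5L)
    expect_equal(halfTotalContributors(7), 1L)
    expect_error(halfTotalContributors(c(0, 0)), "positive")
    set.seed(77)
    for (i in 1:25) {
        v <- round(runif(sample(2:12, 1), 0, 10), 2)
        if (sum(v) == 0) next
        expect_equal(halfTotalContributors(v), oracle_half_total(v),
                     info = paste(v, collapse = ","))
    }
})

test_that("flank metaprofiles recover planted signal and honour the mask", {
    call <- mk_call("chr1", 10000L, "+", full_length = TRUE)
    mcols(call)$pair_distance <- 0L
    # constant signal gives a flat profile of 1 in every bin
    flat <- S4Vectors::SimpleList(
        chr1 = S4Vectors::Rle(1, 20000))
    prof <- flankProfile(flat, call, expressed = TRUE)
    expect_true(all(abs(prof$mean_signal - 1) < 1e-12))
    expect_equal(sort(unique(prof$offset)), seq(-1000, 950, 50))
    # signal exactly over the 1-kb region upstream of the expressed
    # locus's 5' junction (p5 = 9999, so positions 8999-9998)
    up <- S4Vectors::SimpleList(chr1 = S4Vectors::Rle(
        c(0, 1, 0), c(8998, 1000, 10002)))
    calls2 <- c(call, mk_call("chr1", 15000L, "+", full_length = TRUE))
    mcols(calls2)$pair_distance <- c(0L, 0L)
    p2 <- flankProfile(up, calls2, expressed = c(TRUE, FALSE))
    upstream_exp <- p2$mean_signal[p2$group == "expressed" &
                                   p2$extremity == "five_prime" &
                                   p2$offset < 0]
    expect_true(all(upstream_exp == 1))
    expect_true(all(p2$mean_signal[p2$group == "non_expressed"] == 0))
    # masked bins drop out of the aggregation
    mask <- GRanges("chr1", IRanges(10000, 11000))
    pm <- flankProfile(flat, call, expressed = TRUE,
                       internal_mask = mask)
    masked_bins <- pm$mean_signal[pm$extremity == "three_prime" &
                                  pm$offset >= 0]
    expect_true(all(is.nan(masked_bins)))
})

test_that("sample clustering pairs identical replicates and matches direct distances", {
    set.seed(13)
    base <- matrix(runif(30, 0, 5), 10, 3)
    sense <- cbind(base[, 1], base[, 1], base[, 2], base[, 3])
    colnames(sense) <- c("A_R1", "A_R2", "B", "C")
    rownames(sense) <- paste0("L", 1:10)
    le <- mk_le(sense)
    hc <- clusterSamples(le)
    m <- hc$merge
    # the two identical replicates merge first, at height 0
    expect_equal(sort(hc$labels[-m[1, ]]), c("A_R1", "A_R2"))
    expect_equal(hc$height[1], 0)
    # distances agree with a direct pairwise Euclidean computation
    expect_equal(as.matrix(dist(t(sense)))["B", "C"],
                 sqrt(sum((sense[, "B"] - sense[, "C"])^2)))
    expect_error(clusterSamples(mk_le(sense[, 1, drop = FALSE])),
                 "2 samples")
})

test_that("locus clustering uses reciprocal mean FPKM products with neutral distances", {
    sense <- rbind(L1 = c(2, 4, 0), L2 = c(3, 1, 0),
                   L3 = c(0, 0, 4), L4 = c(0, 0, 0), L5 = c(1, 1, 0))
    colnames(sense) <- c("A", "B", "C")
    present <- matrix(TRUE, 5, 3, dimnames = dimnames(sense))
    # L1, L2 and L5 exist only in A and B; L3 only in C
    present[c("L1", "L2", "L5"), "C"] <- FALSE
    present["L3", c("A", "B")] <- FALSE
    le <- mk_le(sense, present = present)
    hc <- clusterLoci(le)
    # locus expressed nowhere is excluded
    expect_false("L4" %in% hc$labels)
    # computable distances: d(L1,L2) = 1/mean(2*3, 4*1) = 0.2 (the stated
    # formula by hand), d(L1,L5) = 1/3, d(L2,L5) = 0.5; L3 shares no
    # sample with the others and gets their mean
    expect_equal(1 / mean(c(2 * 3, 4 * 1)), 0.2)
    # the smallest distance is d(L1,L2): they merge first at that height
    m1 <- hc$merge[1, ]
    expect_setequal(hc$labels[-m1], c("L1", "L2"))
    expect_equal(hc$height[1], 0.2)
})

test_that("planted expression levels are recovered with perfect rank agreement", {
    sim <- small_sim()
    fl <- sim$truth[sim$truth$full_length, ]
    levels <- structure(c(80, 40, 15), names = fl$ins_id[1:3])
    rna <- simulateRnaSeq(sim, sense_levels = levels, n_background = 500,
                          seed = 99)
    calls <- runAtlasPipeline(sim, tags = NULL)$calls
    calls <- calls[mcols(calls)$retained & mcols(calls)$full_length]
    # map calls back to planted loci by coordinate
    ord <- match(start(calls), fl$p3)
    expect_false(anyNA(ord))
    q <- quantifyLoci(rna$frags, calls,
                      total_first_mates = rna$total_first_mates)
    planted <- rna$sense_levels[fl$ins_id[ord]]
    expect_equal(cor(q$sense_fpkm, planted, method = "spearman"), 1,
                 tolerance = 1e-9)
})
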