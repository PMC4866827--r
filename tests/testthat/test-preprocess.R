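ad <- atlasAdapters()
refs3 <- c(linker = unname(ad[["linker"]]), primer = unname(ad[["primer_3p"]]),
           l1_end = unname(ad[["l1_3p_end"]]))
refs5 <- c(linker = unname(ad[["linker"]]), primer = unname(ad[["primer_5p"]]),
           l1_end = unname(ad[["l1_5p_end"]]))

test_that("findAdapter locates exact, mismatched and terminal occurrences", {
    # exact full adapter internally
    m <- findAdapter("CCCCACGTACGTCCCC", "ACGTACGT", 0.12, 4, "anywhere")
    expect_equal(m[c("start", "end", "n_errors")],
                 list(start = 5L, end = 12L, n_errors = 0L))
    # 22-nt adapter: budget floor(0.12 * 22) = 2 substitutions
    set.seed(42)
    adapter <- random_seq(22)
    flank <- "CCGGTTCCGGTTCCGGTTCCGG"
    two <- paste0(flank, mutate_subs(adapter, c(5, 11)))
    three <- paste0(flank, mutate_subs(adapter, c(5, 11, 17)))
    expect_equal(findAdapter(two, adapter, 0.12, 8, "anywhere")$n_errors, 2L)
    expect_null(findAdapter(three, adapter, 0.12, 8, "anywhere"))
    # terminal partial: 8-nt adapter prefix at the read 3' end matches at
    # min_overlap 8, a 7-nt prefix does not
    pre8 <- paste0(flank, substr(adapter, 1, 8))
    pre7 <- paste0(flank, substr(adapter, 1, 7))
    m8 <- findAdapter(pre8, adapter, 0.12, 8, "three_prime")
    expect_equal(m8$matched_len, 8L)
    expect_equal(m8$start, nchar(flank) + 1L)
    expect_null(findAdapter(pre7, adapter, 0.12, 8, "three_prime"))
})

test_that("findAdapter agrees with the exhaustive DP oracle", {
    set.seed(101)
    for (case in 1:60) {
        n <- sample(8:40, 1)
        m <- sample(4:12, 1)
        seq <- random_seq(n)
        adapter <- if (runif(1) < 0.5) random_seq(m) else {
            # plant the adapter (possibly mutated) to exercise hits
            a <- random_seq(m)
            at <- sample(seq_len(max(1, n - m)), 1)
            seq <- paste0(substr(seq, 1, at - 1),
                          if (runif(1) < 0.5) a else
                              mutate_subs(a, sample(m, 1)),
                          substr(seq, at + m, n))
            seq <- substr(seq, 1, n)
            a
        }
        for (anchor in c("anywhere", "three_prime", "five_prime")) {
            rate <- sample(c(0.1, 0.12, 0.2), 1)
            ov <- sample(3:6, 1)
            got <- findAdapter(seq, adapter, rate, ov, anchor)
            want <- oracle_find_adapter(seq, adapter, rate, ov, anchor)
            info <- paste(seq, adapter, anchor, rate, ov)
            if (is.null(want)) expect_null(got, info = info)
            else {
                expect_false(is.null(got), info)
                expect_equal(got$n_errors, want$err, info = info)
                expect_equal(got$matched_len, want$klen, info = info)
            }
        }
    }
})

test_that("quality trimming follows the running-sum rule", {
    q40 <- strrep("I", 20)
    s <- random_seq(20)
    expect_equal(trimQuality3p(s, q40, 12)$seq, s)
    # trailing run of quality 2 removed (brute-force oracle)
    qual <- paste0(strrep("I", 14), strrep("#", 6))
    got <- trimQuality3p(s, qual, 12)
    expect_equal(nchar(got$seq), oracle_quality_trim(qual, 12))
    expect_equal(got$seq, substr(s, 1, 14))
    # random qualities against the oracle
    set.seed(7)
    for (i in 1:30) {
        n <- sample(5:30, 1)
        qual <- intToUtf8(sample(2:41, n, replace = TRUE) + 33L)
        sq <- random_seq(n)
        got <- trimQuality3p(sq, qual, 12)
        expect_equal(nchar(got$seq), oracle_quality_trim(qual, 12))
        expect_equal(nchar(got$seq), nchar(got$qual))
    }
    expect_equal(trimQuality3p("", "", 12)$seq, "")
})

test_that("demultiplexing requires exact barcode prefixes", {
    bcs <- atlasBarcodes(2)
    reads <- data.frame(
        id = c("a", "b", "c"),
        seq = c(paste0(bcs[[1]], strrep("C", 40)),
                paste0(mutate_subs(bcs[[1]], 2), strrep("C", 40)),
                paste0(bcs[[2]], strrep("G", 10))),
        stringsAsFactors = FALSE)
    out <- demultiplexReads(reads, bcs)
    expect_equal(out$reads$id, "a")
    expect_equal(out$reads$seq, strrep("C", 40))  # barcode stripped
    expect_equal(out$reads$sample, "S1")
    expect_equal(out$unassigned, 1L)   # one mismatch -> unassigned
    expect_equal(out$too_short, 1L)    # too short after stripping
    expect_error(demultiplexReads(reads, c(A = "ACGT", B = "ACGT")),
                 "duplicate")
})

test_that("3' trimming decomposes the full read grammar", {
    flank <- paste0(random_seq(57), "CTG")  # junction-side end not A
    read <- paste0(refs3[["linker"]], flank, strrep("A", 15),
                   refs3[["l1_end"]], refs3[["primer"]])
    out <- trimThreePrimeReads(data.frame(id = "x", seq = read))
    expect_true(is.na(out$reason))
    expect_identical(out$flank, flank)
    expect_true(all(unlist(out[, c("linker", "primer", "l1_end", "polyA")])))
    # reads lacking the linker are discarded
    no_link <- trimThreePrimeReads(
        data.frame(id = "y", seq = paste0(flank, strrep("A", 15))))
    expect_equal(no_link$reason, "no_linker")
    # flank shorter than 25 nt after trimming is discarded
    short <- trimThreePrimeReads(data.frame(
        id = "z", seq = paste0(refs3[["linker"]], random_seq(19), "G")))
    expect_equal(short$reason, "too_short")
    # a read with no 3' feature is kept with all feature flags FALSE
    bare <- trimThreePrimeReads(data.frame(
        id = "w", seq = paste0(refs3[["linker"]], random_seq(57), "CTG")))
    expect_true(is.na(bare$reason))
    expect_false(any(unlist(bare[, c("primer", "l1_end", "polyA")])))
})

test_that("5' trimming enforces size selection and full feature grammar", {
    set.seed(3)
    flank <- paste0(random_seq(78), "GC")
    raw <- paste0(refs5[["primer"]], refs5[["l1_end"]],
                  as.character(Biostrings::reverseComplement(
                      Biostrings::DNAString(flank))), refs5[["linker"]])
    expect_gte(nchar(raw), 133)
    out <- trimFivePrimeReads(data.frame(id = "x", seq = raw))
    expect_true(is.na(out$reason))
    expect_identical(out$flank, flank)   # reverse-complemented back
    expect_equal(out$side, "five_prime")
    # below the raw-length cutoff
    short <- trimFivePrimeReads(data.frame(id = "y",
                                           seq = random_seq(120)))
    expect_equal(short$reason, "too_short_raw")
    # linker present but primer missing
    noprim <- trimFivePrimeReads(data.frame(
        id = "z", seq = paste0(random_seq(80), refs5[["l1_end"]],
                               refs5[["linker"]])))
    expect_equal(noprim$reason, "missing_feature")
})

test_that("error-free simulated reads recover planted flanks exactly and trimming is idempotent", {
    sim <- small_sim()
    dm <- demultiplexReads(sim$reads_3p, sim$barcodes)
    trim <- trimThreePrimeReads(dm$reads, refs3)
    prov <- sim$provenance
    orig <- trim[trim$id %in%
                 prov$read_id[prov$class %in%
                              c("junction3p", "nonjunction", "split")], ]
    expect_true(all(is.na(orig$reason)))
    gen <- as.character(sim$genome[[1]])
    aln <- sim$alignments
    idx <- match(orig$id, mcols(aln)$read_id)
    expected <- vapply(seq_along(idx), function(k) {
        a <- aln[idx[k]]
        s <- substr(gen, start(a), end(a))
        if (as.character(strand(a)) == "-")
            as.character(Biostrings::reverseComplement(
                Biostrings::DNAString(s)))
        else s
    }, character(1))
    expect_identical(orig$flank, expected)
    junction <- orig$id %in% prov$read_id[prov$class %in%
                                          c("junction3p", "split")]
    expect_true(all(orig$polyA[junction] & orig$l1_end[junction] &
                    orig$primer[junction]))
    expect_false(any(orig$polyA[!junction] | orig$l1_end[!junction] |
                     orig$primer[!junction]))
    # idempotence: re-trimming a trimmed flank removes nothing
    again <- trimThreePrimeReads(
        data.frame(id = orig$id[1:25],
                   seq = paste0(refs3[["linker"]], orig$flank[1:25])),
        refs3)
    expect_identical(again$flank, orig$flank[1:25])

    # 5' library round-trips the same way
    dm5 <- demultiplexReads(sim$reads_5p, sim$barcodes)
    trim5 <- trimFivePrimeReads(dm5$reads, refs5)
    expect_true(all(is.na(trim5$reason)))
    idx5 <- match(trim5$id, mcols(aln)$read_id)
    expected5 <- vapply(seq_along(idx5), function(k) {
        a <- aln[idx5[k]]
        s <- substr(gen, start(a), end(a))
        if (as.character(strand(a)) == "-")
            as.character(Biostrings::reverseComplement(
                Biostrings::DNAString(s)))
        else s
    }, character(1))
    expect_identical(trim5$flank, expected5)
})
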