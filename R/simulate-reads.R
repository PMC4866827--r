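# Read-level synthetic data: ATLAS junction reads with correct alignments,
# stranded RNA-seq fragments, and consensus-mapped diagnostic reads.

apply_substitutions <- function(seq, rate) {
    if (rate <= 0) return(seq)
    n <- nchar(seq)
    k <- rbinom(1L, n, rate)
    if (k == 0) return(seq)
    pos <- sample.int(n, k)
    ch <- strsplit(seq, "", fixed = TRUE)[[1]]
    for (p in pos)
        ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
    paste(ch, collapse = "")
}

# TRUE when a flank sequence would spuriously lose 3'-terminal bases to
# feature trimming (poly(A) or a chance terminal feature suffix)
flank_trim_risk <- function(flank, refs, config) {
    !is.null(findAdapter(flank, strrep("A", 100L),
                         config@adapter_error_rate, 3L, "three_prime")) ||
    !is.null(findAdapter(flank, refs[["l1_3p_end"]],
                         config@adapter_error_rate,
                         config@min_adapter_overlap, "three_prime")) ||
    !is.null(findAdapter(flank, refs[["primer_3p"]],
                         config@adapter_error_rate,
                         config@min_adapter_overlap, "three_prime"))
}

#' Emit synthetic ATLAS-seq reads and their correct alignments
#'
#' Inverts the read grammar for every planted feature of a synthetic
#' genome: 3' junction reads (barcode + linker + genomic flank + poly(A) +
#' L1 3' end + primer), non-junction reads (no 3' feature), 5' junction
#' reads for full-length insertions (primer + L1 5' end +
#' reverse-complemented flank + linker), spurious-priming decoy reads
#' (flank + primer, no poly(A)/L1), a single low-support read per
#' older-subfamily locus, and split junction reads for transduction pairs
#' whose clipped tail maps downstream of the progenitor. PCR duplicates
#' share the linker position of their template and are shorter (the
#' representative-selection rule recovers the template). Substitution
#' errors are applied at the configured rate. Because the generator knows
#' the truth it also emits each read's correct flank alignment (MAPQ 60),
#' so no external aligner is needed.
#'
#' @param sim Output of \code{\link{makeGenomeAndTruth}}.
#' @param params A \linkS4class{SimulationParams}; defaults to
#'   \code{sim$params}.
#' @return List with \code{reads_3p}, \code{reads_5p} (data.frames
#'   \code{id}, \code{seq}, \code{qual}), \code{alignments} (GRanges with
#'   \code{read_id}, \code{mapq}, \code{is_secondary} and clip fields) and
#'   \code{provenance} (data.frame \code{read_id}, \code{source},
#'   \code{class}).
#' @export
makeAtlasReads <- function(sim, params = sim$params) {
    genome_str <- as.character(sim$genome[[1]])
    G <- nchar(genome_str)
    refs <- sim$refs
    config <- atlasConfig()
    barcode <- atlasBarcodes(1)
    bc <- unname(barcode)
    linker <- refs[["linker"]]
    truth <- sim$truth
    seg <- function(a, b) substr(genome_str, a, b)

    reads3 <- list(); reads5 <- list(); alns <- list(); prov <- list()
    counter <- 0L
    new_id <- function() {
        counter <<- counter + 1L
        sprintf("R%06d", counter)
    }
    emit <- function(list_name, id, seqstr, a, b, strand, source, class,
                     mapq = 60L, clip = NULL) {
        row <- data.frame(id = id, seq = seqstr,
                          qual = strrep("I", nchar(seqstr)),
                          stringsAsFactors = FALSE)
        if (list_name == "3p") reads3[[length(reads3) + 1L]] <<- row
        else reads5[[length(reads5) + 1L]] <<- row
        alns[[length(alns) + 1L]] <<- data.frame(
            start = a, end = b, strand = strand, read_id = id,
            mapq = mapq,
            clip_chrom = if (is.null(clip)) NA_character_ else .SIM_CHROM,
            clip_start = if (is.null(clip)) NA_integer_ else clip$start,
            clip_end = if (is.null(clip)) NA_integer_ else clip$end,
            clip_strand = if (is.null(clip)) NA_character_ else clip$strand,
            clip_mapq = if (is.null(clip)) NA_integer_ else 60L,
            stringsAsFactors = FALSE)
        prov[[length(prov) + 1L]] <<- data.frame(
            read_id = id, source = source, class = class,
            stringsAsFactors = FALSE)
    }
    duplicate_3p <- function(raw, flank_len, a, b, strand, source) {
        n_extra <- rgeom(1L, 1 - params@duplicate_rate)
        for (d in seq_len(n_extra)) {
            Lmin <- nchar(bc) + nchar(linker) + 30L
            L2 <- max(Lmin, round(nchar(raw) * runif(1, 0.6, 0.95)))
            rawd <- substr(raw, 1L, L2)
            fl2 <- min(flank_len, L2 - nchar(bc) - nchar(linker))
            if (strand == "-") { a2 <- b - fl2 + 1L; b2 <- b }
            else { a2 <- a; b2 <- a + fl2 - 1L }
            emit("3p", new_id(),
                 apply_substitutions(rawd, params@substitution_rate),
                 a2, b2, strand, source, "duplicate")
        }
    }

    with_seed(params@seed + 1L, {
        for (i in seq_len(nrow(truth))) {
            t <- truth[i, ]
            lens <- sample(params@flank_len_min:params@flank_len_max,
                           params@reads_per_insertion)
            tail_a <- function() strrep("A", 12L + sample(0:6, 1L))
            for (L in lens) {
                if (t$orientation == "+") {
                    a <- t$p3; b <- t$p3 + L - 1L
                    flank <- revcomp(seg(a, b)); strand <- "-"
                } else {
                    a <- t$p3 - L + 1L; b <- t$p3
                    flank <- seg(a, b); strand <- "+"
                }
                raw <- paste0(bc, linker, flank, tail_a(),
                              refs[["l1_3p_end"]], refs[["primer_3p"]])
                emit("3p", new_id(),
                     apply_substitutions(raw, params@substitution_rate),
                     a, b, strand, t$ins_id, "junction3p")
                duplicate_3p(raw, L, a, b, strand, t$ins_id)
            }
            # reads that stop short of the junction (no 3' feature);
            # linker offsets (distance of the sonication break from the
            # junction) stay unique within a locus so that deduplication
            # restores exactly the template reads
            used_off <- lens
            for (k in seq_len(params@n_nonjunction_reads)) {
                for (try in 1:30) {
                    g <- sample(10:60, 1L)
                    L <- sample(params@flank_len_min:params@flank_len_max,
                                1L)
                    if ((g + L) %in% used_off) next
                    if (t$orientation == "+") {
                        a <- t$p3 + g; b <- a + L - 1L
                        flank <- revcomp(seg(a, b)); strand <- "-"
                    } else {
                        b <- t$p3 - g; a <- b - L + 1L
                        flank <- seg(a, b); strand <- "+"
                    }
                    if (!flank_trim_risk(flank, refs, config)) break
                }
                used_off <- c(used_off, g + L)
                raw <- paste0(bc, linker, flank)
                emit("3p", new_id(),
                     apply_substitutions(raw, params@substitution_rate),
                     a, b, strand, t$ins_id, "nonjunction")
                duplicate_3p(raw, L, a, b, strand, t$ins_id)
            }
            # 5' junction reads for full-length insertions
            if (t$full_length) {
                lens5 <- sample(params@flank_len_min:params@flank_len_max,
                                params@reads_per_insertion_5p)
                for (L in lens5) {
                    if (t$orientation == "+") {
                        a <- t$p5 - L + 1L; b <- t$p5
                        strand <- "+"
                        inner <- revcomp(seg(a, b))
                    } else {
                        a <- t$p5; b <- t$p5 + L - 1L
                        strand <- "-"
                        inner <- seg(a, b)
                    }
                    raw <- paste0(bc, refs[["primer_5p"]],
                                  refs[["l1_5p_end"]], inner, linker)
                    emit("5p", new_id(),
                         apply_substitutions(raw,
                                             params@substitution_rate),
                         a, b, strand, t$ins_id, "five_prime")
                }
            }
            # split reads carrying a 3' transduction from the progenitor
            if (!is.na(t$parent)) {
                pr <- truth[truth$ins_id == t$parent, ]
                split_lens <- params@flank_len_max + sample(10:80, 3L)
                for (k in 1:3) {
                    off <- sample(20:300, 1L)
                    clip <- if (pr$orientation == "+")
                        list(start = pr$p3 + off,
                             end = pr$p3 + off + 59L, strand = "+")
                    else
                        list(start = pr$p3 - off - 59L,
                             end = pr$p3 - off, strand = "-")
                    # flank lengths beyond the regular range so split reads
                    # keep their own linker positions through dedup
                    L <- split_lens[k]
                    if (t$orientation == "+") {
                        a <- t$p3; b <- t$p3 + L - 1L
                        flank <- revcomp(seg(a, b)); strand <- "-"
                    } else {
                        a <- t$p3 - L + 1L; b <- t$p3
                        flank <- seg(a, b); strand <- "+"
                    }
                    raw <- paste0(bc, linker, flank, tail_a(),
                                  refs[["l1_3p_end"]], refs[["primer_3p"]])
                    emit("3p", new_id(),
                         apply_substitutions(raw,
                                             params@substitution_rate),
                         a, b, strand, t$ins_id, "split", clip = clip)
                }
            }
        }
        # spurious primer-priming decoys: flank + primer, no poly(A)/L1
        for (j in seq_along(sim$decoys)) {
            dst <- as.character(strand(sim$decoys))[j]
            Q1 <- start(sim$decoys)[j]; Q2 <- end(sim$decoys)[j]
            lens <- sample(params@flank_len_min:params@flank_len_max, 5L)
            for (L in lens) {
                if (dst == "+") {
                    a <- Q1 - L; b <- Q1 - 1L
                    flank <- seg(a, b); strand <- "+"
                } else {
                    a <- Q2 + 1L; b <- Q2 + L
                    flank <- revcomp(seg(a, b)); strand <- "-"
                }
                raw <- paste0(bc, linker, flank, refs[["primer_3p"]])
                emit("3p", new_id(),
                     apply_substitutions(raw, params@substitution_rate),
                     a, b, strand, sprintf("DECOY_%02d", j), "decoy")
                duplicate_3p(raw, L, a, b, strand,
                             sprintf("DECOY_%02d", j))
            }
        }
        # older-subfamily carry-over: a single weakly supported read
        old <- sim$catalogs$old_subfamily
        for (j in seq_along(old)) {
            p3 <- start(old)[j]
            ostr <- as.character(strand(old))[j]
            L <- sample(params@flank_len_min:params@flank_len_max, 1L)
            if (ostr == "+") {
                a <- p3; b <- p3 + L - 1L
                flank <- revcomp(seg(a, b)); strand <- "-"
            } else {
                a <- p3 - L + 1L; b <- p3
                flank <- seg(a, b); strand <- "+"
            }
            raw <- paste0(bc, linker, flank, strrep("A", 14L),
                          refs[["l1_3p_end"]], refs[["primer_3p"]])
            emit("3p", new_id(),
                 apply_substitutions(raw, params@substitution_rate),
                 a, b, strand, sprintf("PRETA_%02d", j), "preta")
        }
    })

    aln_df <- do.call(rbind, alns)
    si <- GenomeInfoDb::Seqinfo(.SIM_CHROM, G)
    alignments <- GRanges(.SIM_CHROM,
                          IRanges(aln_df$start, aln_df$end),
                          strand = aln_df$strand, seqinfo = si)
    mcols(alignments) <- DataFrame(
        read_id = aln_df$read_id, mapq = aln_df$mapq,
        is_secondary = FALSE,
        clip_chrom = aln_df$clip_chrom, clip_start = aln_df$clip_start,
        clip_end = aln_df$clip_end, clip_strand = aln_df$clip_strand,
        clip_mapq = aln_df$clip_mapq)
    list(reads_3p = do.call(rbind, reads3),
         reads_5p = if (length(reads5)) do.call(rbind, reads5) else
             data.frame(id = character(), seq = character(),
                        qual = character(), stringsAsFactors = FALSE),
         alignments = alignments,
         provenance = do.call(rbind, prov),
         barcodes = barcode)
}

#' Run the full synthetic experiment generator
#'
#' Convenience wrapper: \code{\link{makeGenomeAndTruth}} followed by
#' \code{\link{makeAtlasReads}}.
#'
#' @param params A \linkS4class{SimulationParams}.
#' @return The combined list of both generators' outputs.
#' @export
simulateAtlasExperiment <- function(params = simulationParams()) {
    sim <- makeGenomeAndTruth(params)
    c(sim, makeAtlasReads(sim, params))
}

#' Simulate stranded RNA-seq first-mate fragments around planted loci
#'
#' Places Poisson numbers of first-mate fragments in the 1-kb window
#' downstream of each full-length planted insertion on its sense strand
#' and upstream on the antisense strand (emulating sense readthrough and
#' antisense-promoter activity), plus uniform background fragments
#' genome-wide.
#'
#' @param sim Output of \code{\link{makeGenomeAndTruth}}.
#' @param sense_levels Named numeric vector (names = \code{ins_id} of
#'   full-length insertions): expected fragment counts in the sense
#'   window. Missing loci default to 0.
#' @param antisense_levels Same for the antisense window.
#' @param n_background Number of uniform background fragments.
#' @param frag_len First-mate length (bp).
#' @param window Flanking window size (bp).
#' @param seed RNG seed (default derives from the simulation seed).
#' @return List with \code{frags} (GRanges, \code{mapq} = 60),
#'   \code{total_first_mates}, and the level vectors used.
#' @export
simulateRnaSeq <- function(sim, sense_levels = NULL,
                           antisense_levels = NULL, n_background = 2000L,
                           frag_len = 100L, window = 1000L,
                           seed = sim$params@seed + 2L) {
    truth <- sim$truth
    fl <- truth[truth$full_length, , drop = FALSE]
    lv <- function(x) {
        v <- structure(rep(0, nrow(fl)), names = fl$ins_id)
        if (!is.null(x)) v[names(x)[names(x) %in% names(v)]] <-
            x[names(x) %in% names(v)]
        v
    }
    sense_levels <- lv(sense_levels)
    antisense_levels <- lv(antisense_levels)
    G <- nchar(as.character(sim$genome[[1]]))
    with_seed(seed, {
        pos <- integer(); str <- character()
        place <- function(k, lo, hi, s) {
            if (k <= 0) return()
            pos <<- c(pos, sample(lo:hi, k, replace = TRUE))
            str <<- c(str, rep(s, k))
        }
        for (r in seq_len(nrow(fl))) {
            t <- fl[r, ]
            ks <- rpois(1L, sense_levels[[t$ins_id]])
            ka <- rpois(1L, antisense_levels[[t$ins_id]])
            if (t$orientation == "+") {
                place(ks, t$p3, t$p3 + window - 1L, "+")
                place(ka, t$p5 - window + 1L, t$p5, "-")
            } else {
                place(ks, t$p3 - window + 1L, t$p3, "-")
                place(ka, t$p5, t$p5 + window - 1L, "+")
            }
        }
        if (n_background > 0) {
            pos <- c(pos, sample(seq_len(G - frag_len), n_background,
                                 replace = TRUE))
            str <- c(str, sample(c("+", "-"), n_background,
                                 replace = TRUE))
        }
        # the recorded position is the first mate's 5' end
        start <- ifelse(str == "+", pos, pmax(1L, pos - frag_len + 1L))
        end <- ifelse(str == "+", pmin(G, pos + frag_len - 1L), pos)
        frags <- GRanges(.SIM_CHROM, IRanges(start, end), strand = str,
                         seqinfo = GenomeInfoDb::Seqinfo(.SIM_CHROM, G))
        mcols(frags)$mapq <- 60L
        list(frags = frags, total_first_mates = length(frags),
             sense_levels = sense_levels,
             antisense_levels = antisense_levels)
    })
}

#' Simulate reads aligned to the L1 consensus around the diagnostic site
#'
#' Generates alignment records against the synthetic consensus: reads
#' fully spanning the diagnostic trinucleotide carry ACA/ACG/GAG in the
#' requested proportions; additional reads start elsewhere on the
#' consensus (including some spanning the site only partially).
#'
#' @param n_spanning Number of reads fully spanning the diagnostic triple.
#' @param proportions Named numeric vector of trinucleotide proportions.
#' @param n_offsite Reads mapped elsewhere on the consensus.
#' @param read_len Read length.
#' @param positions Diagnostic positions (1-based).
#' @param seed RNG seed.
#' @return data.frame with \code{start} (1-based consensus position) and
#'   \code{seq}, plus an attribute \code{"planted"} giving the planted
#'   trinucleotide of each spanning read.
#' @export
simulateConsensusReads <- function(n_spanning,
                                   proportions = c(ACA = 0.6, ACG = 0.3,
                                                   GAG = 0.1),
                                   n_offsite = 50L, read_len = 75L,
                                   positions = 5927:5929, seed = 1L) {
    cons <- syntheticL1Consensus()
    with_seed(seed, {
        tri <- sample(names(proportions), n_spanning, replace = TRUE,
                      prob = proportions)
        start <- sample((positions[3] - read_len + 1L):positions[1],
                        n_spanning, replace = TRUE)
        seqs <- vapply(seq_len(n_spanning), function(i) {
            s <- substr(cons, start[i], start[i] + read_len - 1L)
            str_poke(s, positions[1] - start[i] + 1L, tri[i])
        }, character(1))
        # off-site reads never fully span the diagnostic triple (some may
        # touch it partially), so spanning counts come from planted reads
        pool <- setdiff(seq_len(nchar(cons) - read_len + 1L),
                        (positions[3] - read_len + 1L):positions[1])
        off_start <- sample(pool, n_offsite, replace = TRUE)
        off_seqs <- vapply(off_start, function(a)
            substr(cons, a, a + read_len - 1L), character(1))
        out <- data.frame(start = c(start, off_start),
                          seq = c(seqs, off_seqs),
                          stringsAsFactors = FALSE)
        attr(out, "planted") <- tri
        out
    })
}
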