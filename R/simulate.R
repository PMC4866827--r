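#' SimulationParams: synthetic ATLAS-seq experiment parameters
#'
#' Parameters of the synthetic-data generator. The generator plants L1
#' insertions (reference and non-reference, both orientations, full-length
#' and truncated) in a random genome, emits junction reads following the
#' ATLAS read grammar together with their correct alignments, and records
#' complete ground truth, so that every downstream module can be tested
#' against known answers.
#'
#' @slot genome_len background genome length (bp)
#' @slot n_insertions number of planted insertions
#' @slot fraction_full_length fraction of insertions that are full-length
#' @slot fraction_reference fraction present in the reference genome
#' @slot reads_per_insertion non-redundant 3' junction reads per insertion
#' @slot reads_per_insertion_5p non-redundant 5' reads per full-length
#'   insertion
#' @slot n_nonjunction_reads 3' reads per insertion that stop short of the
#'   junction (no trimmable feature)
#' @slot duplicate_rate PCR duplicate rate; each read is replicated
#'   geometrically so the expected raw count is nonredundant/(1 - rate)
#' @slot substitution_rate per-base substitution error rate
#' @slot n_primer_decoys genomic spurious primer-priming decoy loci
#' @slot n_preta planted older-subfamily (carry-over) loci
#' @slot n_transduction_pairs progenitor/progeny pairs linked by split reads
#' @slot n_lineage_insertions full-length reference insertions carrying a
#'   lineage tag in their transduced downstream flank
#' @slot flank_len_min,flank_len_max genomic flank length range (nt)
#' @slot seed RNG seed; all outputs are deterministic given it
#' @exportClass SimulationParams
setClass("SimulationParams", representation(
    genome_len = "integer", n_insertions = "integer",
    fraction_full_length = "numeric", fraction_reference = "numeric",
    reads_per_insertion = "integer", reads_per_insertion_5p = "integer",
    n_nonjunction_reads = "integer", duplicate_rate = "numeric",
    substitution_rate = "numeric", n_primer_decoys = "integer",
    n_preta = "integer", n_transduction_pairs = "integer",
    n_lineage_insertions = "integer", flank_len_min = "integer",
    flank_len_max = "integer", seed = "integer"))

setValidity("SimulationParams", function(object) {
    msg <- character()
    for (nm in c("genome_len", "n_insertions", "reads_per_insertion",
                 "reads_per_insertion_5p", "n_nonjunction_reads",
                 "n_primer_decoys", "n_preta", "n_transduction_pairs",
                 "n_lineage_insertions", "flank_len_min", "flank_len_max"))
        if (slot(object, nm) < 0) msg <- c(msg, paste0(nm, " must be >= 0"))
    for (nm in c("fraction_full_length", "fraction_reference",
                 "duplicate_rate", "substitution_rate")) {
        v <- slot(object, nm)
        if (v < 0 || v > 1) msg <- c(msg, paste0(nm, " must be in [0, 1]"))
    }
    if (object@duplicate_rate >= 1)
        msg <- c(msg, "duplicate_rate must be < 1")
    if (object@flank_len_min > object@flank_len_max)
        msg <- c(msg, "flank_len_min must be <= flank_len_max")
    if (object@flank_len_min < 30L)
        msg <- c(msg, "flank_len_min must be at least 30")
    if (length(msg)) msg else TRUE
})

#' Construct simulation parameters
#'
#' @param ... named overrides of any \linkS4class{SimulationParams} slot.
#' @return A validated \linkS4class{SimulationParams}.
#' @export
simulationParams <- function(...) {
    defaults <- list(
        genome_len = 1000000L, n_insertions = 60L,
        fraction_full_length = 0.3, fraction_reference = 0.6,
        reads_per_insertion = 10L, reads_per_insertion_5p = 5L,
        n_nonjunction_reads = 2L, duplicate_rate = 0.3,
        substitution_rate = 0, n_primer_decoys = 5L,
        n_preta = 3L, n_transduction_pairs = 0L,
        n_lineage_insertions = 0L, flank_len_min = 60L,
        flank_len_max = 250L, seed = 1L)
    ov <- list(...)
    bad <- setdiff(names(ov), names(defaults))
    if (length(bad))
        stop("unknown simulation parameter(s): ", paste(bad, collapse = ", "))
    defaults[names(ov)] <- ov
    int_fields <- c("genome_len", "n_insertions", "reads_per_insertion",
                    "reads_per_insertion_5p", "n_nonjunction_reads",
                    "n_primer_decoys", "n_preta", "n_transduction_pairs",
                    "n_lineage_insertions", "flank_len_min",
                    "flank_len_max", "seed")
    for (nm in int_fields) defaults[[nm]] <- as.integer(defaults[[nm]])
    obj <- do.call(new, c(list("SimulationParams"), defaults))
    validObject(obj)
    obj
}

.SIM_CHROM <- "chrS"
.SIM_SLOT <- 13000L
.SIM_MARGIN <- 9000L

# overwrite bases [at, at+nchar(what)-1] of a sequence string
str_poke <- function(s, at, what) {
    substr(s, at, at + nchar(what) - 1L) <- what
    s
}

#' Generate a synthetic genome with planted insertions and ground truth
#'
#' Builds a random background genome and plants: reference insertions
#' (element body spliced into the sequence, full-length bodies being the
#' synthetic consensus, truncated ones its 3' portion), non-reference
#' insertions (a bare insertion point), spurious primer-priming decoy sites
#' (an exact genomic copy of the 3' primer, alternating strands), and
#' older-subfamily carry-over loci. Full-length reference insertions
#' designated as lineage members receive a transduced segment carrying the
#' lineage tag immediately downstream of their 3' end. The three bases
#' adjacent to every junction are set to a fixed non-A pattern so that
#' poly(A) trimming cannot eat into genomic flank (the inherent ambiguity
#' of a genomic A-run at a junction is not what these tests probe).
#'
#' @param params A \linkS4class{SimulationParams}.
#' @return List with \code{genome} (DNAStringSet, one chromosome),
#'   \code{truth} (data.frame of planted insertions), \code{catalogs}
#'   (GRanges list: \code{reference_l1}, \code{reference_l1_body},
#'   \code{fixed_l1}, \code{known_polymorphic}, \code{genes}, \code{exons},
#'   \code{cnv}, \code{old_subfamily}), \code{decoys} (GRanges of planted
#'   primer sites), \code{consensus}, \code{refs}
#'   (\code{\link{atlasAdapters}}) and \code{params}.
#' @export
makeGenomeAndTruth <- function(params = simulationParams()) {
    stopifnot(is(params, "SimulationParams"))
    validObject(params)
    ad <- atlasAdapters()
    consensus <- syntheticL1Consensus()
    tags <- lineageTags()
    n <- params@n_insertions
    total <- n + params@n_primer_decoys + params@n_preta
    capacity <- (params@genome_len - 2L * .SIM_MARGIN) %/% .SIM_SLOT
    if (total > 0 && capacity < total)
        stop("genome too small for the requested features: need ",
             total * .SIM_SLOT + 2L * .SIM_MARGIN, " bp, have ",
             params@genome_len)
    with_seed(params@seed, {
        bg <- random_dna(params@genome_len)
        kinds <- if (total > 0)
            sample(rep(c("ins", "decoy", "preta"),
                       times = c(n, params@n_primer_decoys,
                                 params@n_preta)))
        else character()
        anchors_bg <- .SIM_MARGIN +
            (seq_len(total) - 1L) * .SIM_SLOT +
            sample(0:2000, total, replace = TRUE)

        # insertion attributes
        ord <- sample(n)
        n_lin <- min(params@n_lineage_insertions, n)
        n_fl <- max(n_lin, round(params@fraction_full_length * n))
        n_ref <- max(n_lin, round(params@fraction_reference * n))
        lineage_of <- rep(NA_character_, n)
        if (n_lin > 0)
            lineage_of[ord[seq_len(n_lin)]] <-
                rep(names(tags), length.out = n_lin)
        full_length <- seq_len(n) %in% ord[seq_len(n_fl)]
        in_ref <- seq_len(n) %in%
            unique(c(ord[seq_len(n_lin)],
                     sample(ord, n_ref)))[seq_len(n_ref)]
        in_ref[!is.na(lineage_of)] <- TRUE
        orientation <- sample(c("+", "-"), n, replace = TRUE)
        trunc_len <- ifelse(full_length, nchar(consensus),
                            sample(500:5500, n, replace = TRUE))
        known_poly <- !in_ref & (runif(n) < 0.5)

        # transduction pairs: progenitor full-length, progeny distinct
        tp <- params@n_transduction_pairs
        parent_of <- rep(NA_integer_, n)
        if (tp > 0) {
            prog_pool <- which(full_length)
            if (length(prog_pool) < 1 || n < 2)
                stop("not enough insertions for transduction pairs")
            progenitors <- sample(prog_pool, tp, replace = TRUE)
            kids_pool <- setdiff(seq_len(n), progenitors)
            if (length(kids_pool) < tp)
                stop("not enough progeny candidates for transduction pairs")
            kids <- sample(kids_pool, tp)
            parent_of[kids] <- progenitors
        }

        # assemble the genome left to right
        pieces <- character(0)
        done <- 0L        # bg consumed so far
        out_len <- 0L     # final genome length so far
        ins_i <- 0L; decoy_i <- 0L; preta_i <- 0L
        truth_rows <- list(); decoy_rows <- list(); preta_rows <- list()
        polish <- list()  # (pos, pattern) edits applied after assembly
        for (k in seq_len(total)) {
            a <- anchors_bg[k]
            pieces <- c(pieces, substr(bg, done + 1L, a - 1L))
            out_len <- out_len + (a - 1L - done)
            done <- a - 1L
            if (kinds[k] == "ins") {
                ins_i <- ins_i + 1L
                i <- ins_i
                elem <- substr(consensus,
                               nchar(consensus) - trunc_len[i] + 1L,
                               nchar(consensus))
                td <- ""
                if (!is.na(lineage_of[i]))
                    td <- paste0("GCG", random_dna(12L),
                                 tags[[lineage_of[i]]], random_dna(15L))
                unit <- paste0(elem, td)
                S <- out_len + 1L
                if (in_ref[i]) {
                    if (orientation[i] == "-") unit <- revcomp(unit)
                    pieces <- c(pieces, unit)
                    out_len <- out_len + nchar(unit)
                    td_len <- nchar(td); blen <- nchar(elem)
                    if (orientation[i] == "+") {
                        body_start <- S; body_end <- S + blen - 1L
                        p3 <- body_end + 1L; p5 <- S - 1L
                    } else {
                        body_start <- S + td_len
                        body_end <- S + nchar(unit) - 1L
                        p3 <- body_start - 1L; p5 <- body_end + 1L
                    }
                } else {
                    body_start <- NA_integer_; body_end <- NA_integer_
                    if (orientation[i] == "+") { p3 <- S; p5 <- S - 1L }
                    else { p3 <- S - 1L; p5 <- S }
                }
                # junction polish: flank bases adjacent to the 3' junction
                if (orientation[i] == "+") polish <- c(polish,
                    list(list(pos = p3, pat = "GCG")))
                else polish <- c(polish,
                    list(list(pos = p3 - 2L, pat = "CGC")))
                truth_rows[[i]] <- data.frame(
                    ins_id = sprintf("INS_%03d", i), chrom = .SIM_CHROM,
                    p3 = p3, p5 = p5, orientation = orientation[i],
                    full_length = full_length[i],
                    truncation_len = trunc_len[i], in_reference = in_ref[i],
                    known_polymorphic = known_poly[i],
                    lineage = lineage_of[i],
                    parent = NA_character_,
                    body_start = body_start, body_end = body_end,
                    stringsAsFactors = FALSE)
            } else if (kinds[k] == "decoy") {
                decoy_i <- decoy_i + 1L
                strand <- if (decoy_i %% 2L == 1L) "+" else "-"
                site <- if (strand == "+") ad[["primer_3p"]] else
                    revcomp(ad[["primer_3p"]])
                S <- out_len + 1L
                pieces <- c(pieces, site)
                out_len <- out_len + nchar(site)
                # flank side: upstream for "+", downstream for "-"
                if (strand == "+") polish <- c(polish,
                    list(list(pos = S - 3L, pat = "CGC")))
                else polish <- c(polish,
                    list(list(pos = S + nchar(site), pat = "GCG")))
                decoy_rows[[decoy_i]] <- data.frame(
                    start = S, end = S + nchar(site) - 1L, strand = strand,
                    stringsAsFactors = FALSE)
            } else {   # preta: older-subfamily 3'-end carry-over locus
                preta_i <- preta_i + 1L
                blen <- 1500L
                elem <- substr(consensus, nchar(consensus) - blen + 1L,
                               nchar(consensus))
                ostr <- if (preta_i %% 2L == 1L) "+" else "-"
                unit <- if (ostr == "+") elem else revcomp(elem)
                S <- out_len + 1L
                pieces <- c(pieces, unit)
                out_len <- out_len + blen
                p3 <- if (ostr == "+") S + blen else S - 1L
                if (ostr == "+") polish <- c(polish,
                    list(list(pos = p3, pat = "GCG")))
                else polish <- c(polish,
                    list(list(pos = p3 - 2L, pat = "CGC")))
                preta_rows[[preta_i]] <- data.frame(
                    p3 = p3, orientation = ostr, stringsAsFactors = FALSE)
            }
        }
        pieces <- c(pieces, substr(bg, done + 1L, nchar(bg)))
        genome_str <- paste(pieces, collapse = "")
        for (e in polish) genome_str <- str_poke(genome_str, e$pos, e$pat)

        truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else
            data.frame(ins_id = character(), chrom = character(),
                       p3 = integer(), p5 = integer(),
                       orientation = character(), full_length = logical(),
                       truncation_len = integer(), in_reference = logical(),
                       known_polymorphic = logical(), lineage = character(),
                       parent = character(), body_start = integer(),
                       body_end = integer(), stringsAsFactors = FALSE)
        if (any(!is.na(parent_of)))
            truth$parent[!is.na(parent_of)] <-
                truth$ins_id[parent_of[!is.na(parent_of)]]

        G <- nchar(genome_str)
        si <- GenomeInfoDb::Seqinfo(.SIM_CHROM, G)
        point_gr <- function(pos, strand = "*", ...) {
            if (length(pos) == 0)
                return(GRanges(seqinfo = si))
            GRanges(.SIM_CHROM, IRanges(pos, width = 1L), strand = strand,
                    seqinfo = si, ...)
        }
        ref <- truth[truth$in_reference, , drop = FALSE]
        reference_l1 <- point_gr(ref$p3, ref$orientation,
                                 ins_id = ref$ins_id)
        body <- ref[!is.na(ref$body_start), , drop = FALSE]
        reference_l1_body <- if (nrow(body))
            GRanges(.SIM_CHROM, IRanges(body$body_start, body$body_end),
                    strand = body$orientation, seqinfo = si,
                    ins_id = body$ins_id)
        else GRanges(seqinfo = si)
        kp <- truth[truth$known_polymorphic, , drop = FALSE]
        known_polymorphic <- point_gr(kp$p3, kp$orientation,
                                      ins_id = kp$ins_id)
        pr <- if (length(preta_rows)) do.call(rbind, preta_rows) else
            data.frame(p3 = integer(), orientation = character())
        old_subfamily <- point_gr(pr$p3, pr$orientation)
        dc <- if (length(decoy_rows)) do.call(rbind, decoy_rows) else
            data.frame(start = integer(), end = integer(),
                       strand = character())
        decoys <- if (nrow(dc))
            GRanges(.SIM_CHROM, IRanges(dc$start, dc$end),
                    strand = dc$strand, seqinfo = si)
        else GRanges(seqinfo = si)

        # background gene/exon/CNV annotation
        n_genes <- max(1L, G %/% 50000L)
        gstart <- sort(sample(seq_len(max(1L, G - 25000L)), n_genes))
        gwidth <- sample(5000:20000, n_genes, replace = TRUE)
        genes <- GRanges(.SIM_CHROM,
                         IRanges(gstart, width = pmin(gwidth, G - gstart)),
                         strand = sample(c("+", "-"), n_genes,
                                         replace = TRUE),
                         seqinfo = si,
                         gene_id = sprintf("GENE_%03d", seq_len(n_genes)))
        exon_list <- lapply(seq_len(n_genes), function(g) {
            ne <- sample(2:4, 1)
            off <- sort(sample(seq_len(max(1L, width(genes)[g] - 400L)),
                               ne))
            IRanges(start(genes)[g] + off - 1L,
                    width = sample(150:300, ne, replace = TRUE))
        })
        exons <- GRanges(.SIM_CHROM, do.call(c, exon_list),
                         seqinfo = si)
        exons <- exons[end(exons) <= G]
        seg <- seq(1L, G, by = 100000L)
        cnv <- GRanges(.SIM_CHROM,
                       IRanges(seg, end = pmin(seg + 99999L, G)),
                       seqinfo = si,
                       state = sample(c("normal", "amplified",
                                        "het_deletion", "uncovered"),
                                      length(seg), replace = TRUE,
                                      prob = c(0.7, 0.1, 0.1, 0.1)))
        genome <- Biostrings::DNAStringSet(structure(genome_str,
                                                     names = .SIM_CHROM))
        list(genome = genome, truth = truth,
             catalogs = list(reference_l1 = reference_l1,
                             reference_l1_body = reference_l1_body,
                             fixed_l1 = reference_l1,
                             known_polymorphic = known_polymorphic,
                             genes = genes, exons = exons, cnv = cnv,
                             old_subfamily = old_subfamily),
             decoys = decoys, consensus = consensus, refs = ad,
             params = params)
    })
}
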