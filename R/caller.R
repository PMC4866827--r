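#' @import GenomicRanges
#' @import SummarizedExperiment
#' @import IRanges
#' @import S4Vectors
NULL

# required metadata columns of a mapped-read GRanges
.aln_required <- c("read_id", "mapq", "is_secondary")

check_alignments <- function(gr) {
    stopifnot(is(gr, "GRanges"))
    miss <- setdiff(.aln_required, names(mcols(gr)))
    if (length(miss))
        stop("alignments lack metadata column(s): ",
             paste(miss, collapse = ", "))
    invisible(gr)
}

#' Attach trimming feature flags to mapped flank reads
#'
#' Joins the per-read sidecar produced by the trimming step onto an
#' alignment GRanges by read id, keeping only reads that were retained by
#' trimming.
#'
#' @param alignments GRanges of mapped flank reads with an mcols column
#'   \code{read_id}.
#' @param trimmed data.frame from \code{\link{trimThreePrimeReads}} /
#'   \code{\link{trimFivePrimeReads}}.
#' @return The subset of \code{alignments} whose reads were kept, with
#'   \code{side}, \code{polyA}, \code{l1_end}, \code{primer} and
#'   \code{sample} columns added.
#' @export
joinTrimInfo <- function(alignments, trimmed) {
    check_alignments(alignments)
    kept <- trimmed[is.na(trimmed$reason), , drop = FALSE]
    idx <- match(mcols(alignments)$read_id, kept$id)
    out <- alignments[!is.na(idx)]
    k <- idx[!is.na(idx)]
    mcols(out)$side <- kept$side[k]
    mcols(out)$polyA <- kept$polyA[k]
    mcols(out)$l1_end <- kept$l1_end[k]
    mcols(out)$primer <- kept$primer[k]
    mcols(out)$sample <- kept$sample[k]
    out
}

#' Remove secondary and ambiguously mapped reads
#'
#' Secondary alignments are dropped, as are reads whose mapping quality is
#' less than or equal to \code{mapq_min} (the bound is exclusive: MAPQ 20 is
#' removed at the default, MAPQ 21 kept).
#'
#' @param alignments GRanges of mapped reads (see package overview for the
#'   expected mcols).
#' @param mapq_min Exclusive MAPQ lower bound.
#' @return Filtered GRanges.
#' @export
filterAlignments <- function(alignments, mapq_min = 20) {
    check_alignments(alignments)
    alignments[!mcols(alignments)$is_secondary &
               mcols(alignments)$mapq > mapq_min]
}

#' Genomic linker position of mapped flank reads
#'
#' The linker marks the sonication break of the original genomic fragment;
#' reads sharing it are PCR duplicates. The linker end of a trimmed flank is
#' its flank-distal end: the leftmost mapped base for plus-strand
#' alignments, the rightmost for minus-strand alignments.
#'
#' @param alignments GRanges of mapped flank reads.
#' @return Integer vector of linker positions.
#' @export
linkerPosition <- function(alignments) {
    ifelse(as.character(strand(alignments)) == "+",
           start(alignments), end(alignments))
}

#' Remove PCR duplicates by linker position
#'
#' Reads are redundant when they map to the same chromosome and strand and
#' start from the same linker position. Each redundant group is reduced to
#' its longest member; ties are broken deterministically by the
#' lexicographically smallest read id. The group size is recorded in an
#' \code{n_dup} column so redundant (RPM) and non-redundant (TPM) counts
#' stay available downstream.
#'
#' @param alignments GRanges of mapped, filtered flank reads.
#' @return GRanges of representative reads with an added \code{n_dup}
#'   column, in sorted order.
#' @export
deduplicateReads <- function(alignments) {
    check_alignments(alignments)
    if (length(alignments) == 0) {
        mcols(alignments)$n_dup <- integer()
        return(alignments)
    }
    key <- paste(seqnames(alignments), strand(alignments),
                 linkerPosition(alignments), sep = "\r")
    grp <- split(seq_along(alignments), key)
    keep <- vapply(grp, function(ii) {
        w <- width(alignments)[ii]
        cand <- ii[w == max(w)]
        cand[order(mcols(alignments)$read_id[cand])][1L]
    }, integer(1))
    ndup <- lengths(grp)
    out <- alignments[keep]
    mcols(out)$n_dup <- as.integer(ndup)
    sort(out, ignore.strand = TRUE)
}

#' Cluster non-redundant reads into putative insertion clusters
#'
#' Same-strand reads that overlap or are separated by at most
#' \code{gap} bp are merged into one cluster (bedtools-merge \code{-s -d}
#' semantics; a separation of exactly \code{gap} merges, \code{gap + 1}
#' does not). The cluster span is the union hull of its members.
#'
#' @param alignments Deduplicated GRanges, coordinate-sorted (an error is
#'   raised otherwise), with \code{n_dup}, \code{polyA}, \code{l1_end} and
#'   \code{primer} mcols.
#' @param side \code{"three_prime"} or \code{"five_prime"}.
#' @param gap Maximum merge distance in bp.
#' @return GRanges of clusters with mcols \code{cluster_id}, \code{side},
#'   \code{n_nonredundant}, \code{n_redundant}, \code{n_polyA_or_l1},
#'   \code{n_primer_only} and \code{member_ids} (CharacterList).
#' @export
clusterReads <- function(alignments, side = c("three_prime", "five_prime"),
                         gap = 100) {
    side <- match.arg(side)
    check_alignments(alignments)
    if (length(alignments) > 1 && is.unsorted(alignments, ignore.strand = TRUE))
        stop("alignments must be coordinate-sorted before clustering")
    mc <- mcols(alignments)
    ndup <- if (!is.null(mc$n_dup)) mc$n_dup else rep(1L, length(alignments))
    red <- GenomicRanges::reduce(alignments, min.gapwidth = gap + 1L,
                                 with.revmap = TRUE)
    rev <- mcols(red)$revmap
    polyA_or_l1 <- (mc$polyA %in% TRUE) | (mc$l1_end %in% TRUE)
    primer_only <- (mc$primer %in% TRUE) & !polyA_or_l1
    out <- granges(red)
    mcols(out) <- DataFrame(
        cluster_id = sprintf("%s_%s_%d_%s",
                             ifelse(side == "three_prime", "c3p", "c5p"),
                             seqnames(red), start(red), strand(red)),
        side = side,
        n_nonredundant = lengths(rev),
        n_redundant = vapply(rev, function(ii) sum(ndup[ii]), integer(1)),
        n_polyA_or_l1 = vapply(rev, function(ii)
            sum(polyA_or_l1[ii]), integer(1)),
        n_primer_only = vapply(rev, function(ii)
            sum(primer_only[ii]), integer(1)),
        member_ids = as(lapply(rev, function(ii) mc$read_id[ii]),
                        "CharacterList"))
    out
}

#' Add per-million normalized counts to clusters
#'
#' RPM is the redundant read count per million mapped (redundant) reads;
#' TPM is the non-redundant count per million mapped non-redundant reads.
#'
#' @param clusters GRanges from \code{\link{clusterReads}}.
#' @param total_redundant,total_nonredundant Library-wide totals of mapped
#'   redundant and non-redundant reads.
#' @return \code{clusters} with \code{rpm} and \code{tpm} columns.
#' @export
normalizeCounts <- function(clusters, total_redundant, total_nonredundant) {
    if (total_redundant <= 0 || total_nonredundant <= 0)
        stop("normalization totals must be strictly positive")
    mcols(clusters)$rpm <-
        mcols(clusters)$n_redundant / total_redundant * 1e6
    mcols(clusters)$tpm <-
        mcols(clusters)$n_nonredundant / total_nonredundant * 1e6
    clusters
}

#' Derive insertion point and L1 orientation from read clusters
#'
#' 3'-ATLAS flank reads map antisense to the element they flank, so a 3'
#' cluster on the minus strand supports a sense (+) L1 and its insertion
#' point is the most upstream cluster coordinate; a 3' cluster on the plus
#' strand supports an antisense (-) L1 with the point at the most
#' downstream coordinate. 5' clusters are mirrored (plus-strand 5' cluster
#' -> sense L1, point at the most downstream coordinate).
#'
#' @param clusters GRanges from \code{\link{clusterReads}}.
#' @return GRanges of width-1 insertion points, strand = L1 orientation,
#'   carrying the cluster bookkeeping (\code{call_id}, \code{side},
#'   cluster span and counts).
#' @export
callInsertionPoints <- function(clusters) {
    mc <- mcols(clusters)
    side <- mc$side
    cl_strand <- as.character(strand(clusters))
    orientation <- ifelse(side == "three_prime",
                          ifelse(cl_strand == "-", "+", "-"),
                          ifelse(cl_strand == "+", "+", "-"))
    upstream <- (side == "three_prime" & orientation == "+") |
                (side == "five_prime" & orientation == "-")
    point <- ifelse(upstream, start(clusters), end(clusters))
    out <- GRanges(seqnames(clusters), IRanges(point, width = 1L),
                   strand = orientation,
                   seqinfo = seqinfo(clusters))
    mcols(out) <- DataFrame(
        call_id = sprintf("%s|%s:%d:%s", side, seqnames(clusters),
                          point, orientation),
        side = side,
        cluster_start = start(clusters),
        cluster_end = end(clusters),
        cluster_strand = cl_strand,
        mc[setdiff(names(mc), c("side", "cluster_id"))])
    sort(out, ignore.strand = TRUE)
}

#' Pair 3' calls with 5' clusters into full-length insertions
#'
#' For each 3' call, orientation-compatible 5' clusters whose called 5'-end
#' point lies within \code{window} bp upstream (in the L1 sense direction)
#' of the 3' integration site are candidate mates. The pairing distance is
#' the genomic span strictly between the two junction points: close to the
#' element length (about 6 kb) when the element body is present in the
#' reference sequence, close to 0 for non-reference insertions. Each 5'
#' cluster pairs with at most one 3' call; assignment is globally greedy by
#' increasing distance, so the nearest compatible mate wins.
#'
#' @param calls3p GRanges of 3' calls from \code{\link{callInsertionPoints}}.
#' @param clusters5p GRanges of 5' clusters from \code{\link{clusterReads}}.
#' @param window Maximum pairing distance in bp.
#' @return \code{calls3p} with \code{full_length}, \code{pair_distance},
#'   \code{n_nonredundant_5p} and \code{five_prime_call_id} columns.
#' @export
pairFullLength <- function(calls3p, clusters5p, window = 7000) {
    n <- length(calls3p)
    mcols(calls3p)$full_length <- rep(FALSE, n)
    mcols(calls3p)$pair_distance <- rep(NA_integer_, n)
    mcols(calls3p)$n_nonredundant_5p <- rep(0L, n)
    mcols(calls3p)$five_prime_call_id <- rep(NA_character_, n)
    if (n == 0 || length(clusters5p) == 0) return(calls3p)
    calls5p <- callInsertionPoints(clusters5p)
    cand <- expand.grid(i3 = seq_len(n), i5 = seq_along(calls5p))
    same <- as.character(seqnames(calls3p))[cand$i3] ==
                as.character(seqnames(calls5p))[cand$i5] &
            as.character(strand(calls3p))[cand$i3] ==
                as.character(strand(calls5p))[cand$i5]
    cand <- cand[same, , drop = FALSE]
    p3 <- start(calls3p)[cand$i3]
    p5 <- start(calls5p)[cand$i5]
    plus <- as.character(strand(calls3p))[cand$i3] == "+"
    d <- ifelse(plus, p3 - p5, p5 - p3) - 1L
    ok <- d >= 0 & d <= window
    cand <- cand[ok, , drop = FALSE]; d <- d[ok]
    o <- order(d, cand$i3, cand$i5)
    used3 <- logical(n); used5 <- logical(length(calls5p))
    for (k in o) {
        i3 <- cand$i3[k]; i5 <- cand$i5[k]
        if (used3[i3] || used5[i5]) next
        used3[i3] <- TRUE; used5[i5] <- TRUE
        mcols(calls3p)$full_length[i3] <- TRUE
        mcols(calls3p)$pair_distance[i3] <- d[k]
        mcols(calls3p)$n_nonredundant_5p[i3] <-
            mcols(calls5p)$n_nonredundant[i5]
        mcols(calls3p)$five_prime_call_id[i3] <-
            mcols(calls5p)$call_id[i5]
    }
    calls3p
}

# distance from each call point to the nearest feature of a catalog;
# Inf when the catalog is empty or has no feature on the call's chromosome
.nearest_distance <- function(calls, catalog) {
    out <- rep(Inf, length(calls))
    if (is.null(catalog) || length(catalog) == 0) return(out)
    hit <- distanceToNearest(calls, catalog, ignore.strand = TRUE)
    out[queryHits(hit)] <- mcols(hit)$distance
    out
}

#' Annotate insertion calls against reference and polymorphism catalogs
#'
#' A call matches a catalogued insertion when it falls within
#' \code{window} bp of it. \code{known_status} is \code{"reference"} when
#' the call matches a reference-genome L1 annotation,
#' \code{"known_polymorphic"} when it matches a known polymorphic insertion,
#' and \code{"novel"} otherwise. Gene context records the call's orientation
#' relative to overlapping genes; CNV state is taken from the overlapping
#' copy-number segment (\code{"unknown"} when uncovered by the CNV track).
#'
#' @param calls GRanges of insertion calls.
#' @param catalogs Named list of GRanges; recognized elements:
#'   \code{reference_l1} (reference L1 3' ends), \code{known_polymorphic},
#'   \code{genes} (stranded) and \code{cnv} (with a \code{state} mcols
#'   column).
#' @param window Matching window in bp.
#' @return \code{calls} with \code{is_reference}, \code{known_status},
#'   \code{gene_context} and \code{cnv_state} columns.
#' @export
annotateCalls <- function(calls, catalogs, window = 200) {
    d_ref <- .nearest_distance(calls, catalogs$reference_l1)
    d_pol <- .nearest_distance(calls, catalogs$known_polymorphic)
    is_ref <- d_ref <= window
    status <- ifelse(is_ref, "reference",
                     ifelse(d_pol <= window, "known_polymorphic", "novel"))
    gene_context <- rep("intergenic", length(calls))
    if (!is.null(catalogs$genes) && length(catalogs$genes) > 0) {
        ov <- findOverlaps(calls, catalogs$genes, ignore.strand = TRUE)
        gs <- as.character(strand(catalogs$genes))[subjectHits(ov)]
        cs <- as.character(strand(calls))[queryHits(ov)]
        rel <- ifelse(gs == "*" | cs == gs, "sense", "antisense")
        for (i in unique(queryHits(ov))) {
            r <- unique(rel[queryHits(ov) == i])
            gene_context[i] <- if (length(r) > 1) "genic_both"
                               else paste0("genic_", r)
        }
    }
    cnv_state <- rep("unknown", length(calls))
    if (!is.null(catalogs$cnv) && length(catalogs$cnv) > 0) {
        ov <- findOverlaps(calls, catalogs$cnv, ignore.strand = TRUE)
        cnv_state[queryHits(ov)] <-
            mcols(catalogs$cnv)$state[subjectHits(ov)]
    }
    mcols(calls)$is_reference <- is_ref
    mcols(calls)$known_status <- status
    mcols(calls)$gene_context <- gene_context
    mcols(calls)$cnv_state <- cnv_state
    calls
}
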