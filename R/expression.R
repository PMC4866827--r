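#' LocusExpression: per-locus, per-sample flanking-window expression
#'
#' A \linkS4class{SummarizedExperiment} subclass holding sense and antisense
#' flanking-window FPKM for full-length L1 loci (rows) across samples
#' (columns), together with a logical \code{present} assay recording whether
#' the (possibly polymorphic) locus exists in each sample's genome. FPKM
#' assays carry \code{NA} at absent loci: absence is a distinguished state,
#' never conflated with an FPKM of 0. The FPKM threshold used to call a
#' locus expressed is stored in \code{metadata()$expressed_fpkm_threshold}.
#'
#' @exportClass LocusExpression
setClass("LocusExpression",
         contains = "SummarizedExperiment")

setValidity("LocusExpression", function(object) {
    msg <- character()
    need <- c("sense_fpkm", "antisense_fpkm", "present")
    miss <- setdiff(need, SummarizedExperiment::assayNames(object))
    if (length(miss))
        msg <- c(msg, paste("missing assay(s):", paste(miss, collapse = ", ")))
    if (!length(miss)) {
        p <- SummarizedExperiment::assay(object, "present")
        s <- SummarizedExperiment::assay(object, "sense_fpkm")
        a <- SummarizedExperiment::assay(object, "antisense_fpkm")
        if (!is.logical(p)) msg <- c(msg, "'present' must be logical")
        if (any(!is.na(s) & s < 0) || any(!is.na(a) & a < 0))
            msg <- c(msg, "FPKM values must be non-negative")
        if (any(p & (is.na(s) | is.na(a))))
            msg <- c(msg, "present loci must have FPKM values")
        if (any(!p & (!is.na(s) | !is.na(a))))
            msg <- c(msg, "absent loci must carry NA FPKM, not numbers")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a LocusExpression object
#'
#' @param sense_fpkm,antisense_fpkm Numeric matrices (loci x samples);
#'   entries at absent loci are forced to \code{NA}.
#' @param present Logical matrix of the same shape; default all
#'   \code{TRUE}.
#' @param threshold FPKM threshold above which a present locus is called
#'   expressed.
#' @param rowData Optional DataFrame/data.frame of per-locus annotation.
#' @return A \linkS4class{LocusExpression}.
#' @export
#' @examples
#' m <- matrix(c(0.2, 0, 0.8, 0.01), 2, 2,
#'             dimnames = list(c("L1", "L2"), c("A", "B")))
#' le <- LocusExpression(m, m * 0.1)
#' isExpressed(le)
LocusExpression <- function(sense_fpkm, antisense_fpkm,
                            present = NULL, threshold = 0.05,
                            rowData = NULL) {
    sense_fpkm <- as.matrix(sense_fpkm)
    antisense_fpkm <- as.matrix(antisense_fpkm)
    if (is.null(present))
        present <- matrix(TRUE, nrow(sense_fpkm), ncol(sense_fpkm),
                          dimnames = dimnames(sense_fpkm))
    present <- as.matrix(present)
    sense_fpkm[!present] <- NA_real_
    antisense_fpkm[!present] <- NA_real_
    args <- list(assays = list(sense_fpkm = sense_fpkm,
                               antisense_fpkm = antisense_fpkm,
                               present = present),
                 metadata = list(expressed_fpkm_threshold = threshold))
    if (!is.null(rowData)) args$rowData <- rowData
    se <- do.call(SummarizedExperiment::SummarizedExperiment, args)
    new("LocusExpression", se)
}

#' @describeIn LocusExpression-accessors sense-strand flanking FPKM matrix
#'   (\code{NA} at absent loci).
#' @export
senseFPKM <- function(x) SummarizedExperiment::assay(x, "sense_fpkm")

#' @describeIn LocusExpression-accessors antisense flanking FPKM matrix.
#' @export
antisenseFPKM <- function(x) SummarizedExperiment::assay(x, "antisense_fpkm")

#' @describeIn LocusExpression-accessors logical matrix: is the locus
#'   present in the sample's genome?
#' @export
isPresent <- function(x) SummarizedExperiment::assay(x, "present")

#' Accessors for LocusExpression objects
#'
#' @param x A \linkS4class{LocusExpression}.
#' @param threshold FPKM threshold; defaults to the one stored in the
#'   object.
#' @return \code{isExpressed} returns a logical matrix: \code{TRUE} when the
#'   locus is present and its sense FPKM strictly exceeds the threshold
#'   (a locus exactly at the threshold is non-expressed), \code{FALSE} when
#'   present but at or below it, and \code{NA} where the locus is absent
#'   from the sample's genome (absent loci belong to neither group).
#' @name LocusExpression-accessors
#' @export
isExpressed <- function(x, threshold = NULL) {
    if (is.null(threshold))
        threshold <- S4Vectors::metadata(x)$expressed_fpkm_threshold
    s <- senseFPKM(x)
    out <- !is.na(s) & s > threshold
    out[!isPresent(x)] <- NA
    out
}

#' Classify loci as expressed or non-expressed
#'
#' Materializes the expressed/non-expressed dichotomy at the given FPKM
#' threshold as an \code{expressed} assay (with \code{NA} at absent loci)
#' and records the threshold in the object metadata.
#'
#' @param x A \linkS4class{LocusExpression}.
#' @param threshold FPKM threshold (strictly-greater rule).
#' @return The updated object.
#' @export
classifyExpressed <- function(x, threshold = 0.05) {
    S4Vectors::metadata(x)$expressed_fpkm_threshold <- threshold
    SummarizedExperiment::assay(x, "expressed") <- isExpressed(x, threshold)
    x
}

setMethod("show", "LocusExpression", function(object) {
    ex <- isExpressed(object)
    cat("LocusExpression:", nrow(object), "loci x", ncol(object),
        "samples\n")
    cat("  expressed threshold:",
        S4Vectors::metadata(object)$expressed_fpkm_threshold, "FPKM\n")
    cat("  expressed locus-sample pairs:", sum(ex, na.rm = TRUE),
        "| absent pairs:", sum(!isPresent(object)), "\n")
})

# 5' position of a fragment's first mate
.frag_pos <- function(frags) {
    ifelse(as.character(strand(frags)) == "+", start(frags), end(frags))
}

#' Flanking-window expression of one sample's loci
#'
#' For each full-length call, counts stranded RNA-seq first mates whose 5'
#' position falls in the 1-kb window immediately downstream of the 3'
#' junction on the element's sense strand (sense transcription readthrough)
#' and in the 1-kb window immediately upstream of the 5' junction on the
#' opposite strand (antisense-promoter activity). Mates need MAPQ at or
#' above \code{mapq_min}; fragments overlapping masked exons are excluded.
#' FPKM is the window count per million mapped first mates per kb of
#' window (the window length stays fixed at 1 kb; masking does not rescale
#' it).
#'
#' @param frags GRanges of first-mate fragments (strand = transcribed
#'   strand, \code{mapq} mcols column).
#' @param calls GRanges of full-length 3' calls (strand = L1 orientation,
#'   \code{pair_distance} column locating the 5' junction).
#' @param exons Optional GRanges of exons to mask.
#' @param total_first_mates Library total of mapped first mates.
#' @param config An \linkS4class{AtlasConfig}.
#' @return data.frame with \code{call_id}, \code{sense_fpkm},
#'   \code{antisense_fpkm}.
#' @export
quantifyLoci <- function(frags, calls, exons = NULL, total_first_mates,
                         config = atlasConfig()) {
    if (total_first_mates <= 0)
        stop("total_first_mates must be strictly positive")
    w <- config@expression_flank
    if (!is.null(mcols(frags)$mapq))
        frags <- frags[mcols(frags)$mapq >= config@mapq_min_rna]
    if (!is.null(exons) && length(exons) > 0)
        frags <- frags[!overlapsAny(frags, exons, ignore.strand = TRUE)]
    pos <- .frag_pos(frags)
    fchr <- as.character(seqnames(frags))
    fstr <- as.character(strand(frags))
    p3 <- start(calls)
    ori <- as.character(strand(calls))
    pd <- mcols(calls)$pair_distance
    if (is.null(pd)) pd <- rep(NA_integer_, length(calls))
    p5 <- ifelse(ori == "+", p3 - pd - 1L, p3 + pd + 1L)
    n <- length(calls)
    sense <- antisense <- numeric(n)
    for (i in seq_len(n)) {
        chr <- as.character(seqnames(calls))[i]
        if (ori[i] == "+") {
            s_lo <- p3[i]; s_hi <- p3[i] + w - 1L; s_str <- "+"
            a_lo <- p5[i] - w + 1L; a_hi <- p5[i]; a_str <- "-"
        } else {
            s_lo <- p3[i] - w + 1L; s_hi <- p3[i]; s_str <- "-"
            a_lo <- p5[i]; a_hi <- p5[i] + w - 1L; a_str <- "+"
        }
        in_chr <- fchr == chr
        sense[i] <- sum(in_chr & fstr == s_str & pos >= s_lo & pos <= s_hi)
        antisense[i] <- if (is.na(p5[i])) NA_real_ else
            sum(in_chr & fstr == a_str & pos >= a_lo & pos <= a_hi)
    }
    scale <- (total_first_mates / 1e6) * (w / 1000)
    data.frame(call_id = mcols(calls)$call_id,
               sense_fpkm = sense / scale,
               antisense_fpkm = antisense / scale,
               stringsAsFactors = FALSE)
}

#' Count subfamily-diagnostic trinucleotides in consensus alignments
#'
#' Reads aligned end-to-end against the L1 consensus vote for the subfamily
#' they derive from through the trinucleotide their alignment spells at the
#' diagnostic consensus positions (default 5927-5929, 1-based): ACA marks
#' the youngest (transposition-active) subfamily, ACG its predecessor, GAG
#' older families. Reads spanning only part of the triple are not counted
#' (reported as \code{partial}). Counts are normalized per million reads
#' mapped to the whole genome.
#'
#' @param alignments data.frame with \code{start} (1-based leftmost
#'   consensus position) and \code{seq} (aligned sequence, consensus
#'   strand).
#' @param positions Integer vector of three contiguous 1-based consensus
#'   positions.
#' @param total_genome_mapped Total reads mapped to the reference genome.
#' @return List of class \code{"SubfamilyCounts"}: \code{counts} (named ACA,
#'   ACG, GAG, other), \code{partial}, \code{total_mapped_genome} and
#'   \code{per_million}.
#' @export
countDiagnosticTrinucleotides <- function(alignments,
                                          positions = 5927:5929,
                                          total_genome_mapped) {
    stopifnot(length(positions) == 3, all(diff(positions) == 1))
    if (total_genome_mapped <= 0)
        stop("total_genome_mapped must be strictly positive")
    counts <- c(ACA = 0L, ACG = 0L, GAG = 0L, other = 0L)
    partial <- 0L
    if (nrow(alignments)) {
        ends <- alignments$start + nchar(alignments$seq) - 1L
        spans <- alignments$start <= positions[1] & ends >= positions[3]
        touches <- alignments$start <= positions[3] & ends >= positions[1]
        partial <- sum(touches & !spans)
        off <- positions[1] - alignments$start[spans] + 1L
        tri <- substr(alignments$seq[spans], off, off + 2L)
        for (t in tri) {
            if (t %in% names(counts)) counts[t] <- counts[t] + 1L
            else counts["other"] <- counts["other"] + 1L
        }
    }
    structure(list(counts = counts, partial = partial,
                   total_mapped_genome = total_genome_mapped,
                   per_million = counts / total_genome_mapped * 1e6),
              class = "SubfamilyCounts")
}

#' @export
print.SubfamilyCounts <- function(x, ...) {
    cat("Subfamily-diagnostic trinucleotide counts",
        sprintf("(per %g genome-mapped reads)\n", x$total_mapped_genome))
    for (nm in names(x$counts))
        cat(sprintf("  %-6s %8d  (%.3f per million)\n", nm, x$counts[[nm]],
                    x$per_million[[nm]]))
    cat("  partial-span reads ignored:", x$partial, "\n")
    invisible(x)
}

#' Number of loci contributing half of the total expression
#'
#' The smallest number k of loci such that the k most expressed ones
#' account for at least half of the summed FPKM.
#'
#' @param fpkm Non-negative numeric vector with a positive sum.
#' @return Integer k.
#' @export
#' @examples
#' halfTotalContributors(c(4, 3, 2, 1))  # 2
halfTotalContributors <- function(fpkm) {
    fpkm <- fpkm[!is.na(fpkm)]
    if (length(fpkm) == 0 || any(fpkm < 0))
        stop("fpkm must be a non-empty non-negative vector")
    tot <- sum(fpkm)
    if (tot <= 0) stop("total FPKM must be positive")
    cs <- cumsum(sort(fpkm, decreasing = TRUE))
    which(cs >= tot / 2)[1]
}

#' Mean signal metaprofiles around element extremities
#'
#' Averages a per-base signal track in fixed-width bins across the 1-kb
#' regions flanking each element extremity (5' and 3' junctions), oriented
#' in the element's sense direction, separately for expressed and
#' non-expressed loci. Positions falling inside masked internal element
#' bodies contribute nothing (only flanks are aggregated).
#'
#' @param signal Named \code{RleList} (or \code{SimpleRleList}) of per-base
#'   coverage, as returned by \code{GenomicRanges::coverage}.
#' @param calls GRanges of full-length 3' calls (with
#'   \code{pair_distance}).
#' @param expressed Logical vector parallel to \code{calls}.
#' @param internal_mask Optional GRanges of element bodies to exclude.
#' @param config An \linkS4class{AtlasConfig} (bin width, flank size).
#' @return data.frame with \code{group}, \code{extremity}
#'   (\code{"five_prime"}/\code{"three_prime"}), \code{offset} (bin start
#'   offset relative to the junction, in the element's sense direction)
#'   and \code{mean_signal}.
#' @export
flankProfile <- function(signal, calls, expressed, internal_mask = NULL,
                         config = atlasConfig()) {
    w <- config@expression_flank
    bin <- config@profile_bin
    nbins <- 2L * w %/% bin
    offsets <- seq(-w, w - bin, by = bin)
    masked <- function(chr, lo, hi) {
        if (is.null(internal_mask) || length(internal_mask) == 0)
            return(FALSE)
        overlapsAny(GRanges(chr, IRanges(lo, hi)), internal_mask,
                    ignore.strand = TRUE)
    }
    acc <- list()
    p3 <- start(calls)
    ori <- as.character(strand(calls))
    pd <- mcols(calls)$pair_distance
    p5 <- ifelse(ori == "+", p3 - pd - 1L, p3 + pd + 1L)
    for (i in seq_along(calls)) {
        chr <- as.character(seqnames(calls))[i]
        if (!chr %in% names(signal)) next
        sig <- signal[[chr]]
        for (ext in c("five_prime", "three_prime")) {
            junction <- if (ext == "five_prime") p5[i] else p3[i]
            if (is.na(junction)) next
            vals <- numeric(nbins)
            ok <- logical(nbins)
            for (b in seq_len(nbins)) {
                # offset measured in the element's sense direction
                lo_off <- offsets[b]
                gp <- if (ori[i] == "+") junction + lo_off else
                    junction - lo_off - bin + 1L
                gpos <- gp:(gp + bin - 1L)
                gpos <- gpos[gpos >= 1 & gpos <= length(sig)]
                if (length(gpos) == 0) next
                if (masked(chr, min(gpos), max(gpos))) next
                vals[b] <- mean(as.numeric(sig[gpos]))
                ok[b] <- TRUE
            }
            grp <- if (isTRUE(expressed[i])) "expressed" else "non_expressed"
            acc[[length(acc) + 1L]] <- data.frame(
                group = grp, extremity = ext, offset = offsets,
                signal = ifelse(ok, vals, NA_real_),
                stringsAsFactors = FALSE)
        }
    }
    if (length(acc) == 0)
        return(data.frame(group = character(), extremity = character(),
                          offset = integer(), mean_signal = numeric()))
    all <- do.call(rbind, acc)
    out <- aggregate(signal ~ group + extremity + offset, data = all,
                     FUN = function(v) mean(v, na.rm = TRUE))
    names(out)[names(out) == "signal"] <- "mean_signal"
    out[order(out$group, out$extremity, out$offset), , drop = FALSE]
}

#' Hierarchical clustering of samples by locus expression profile
#'
#' Euclidean distance between per-sample sense-FPKM vectors (absent loci
#' contribute 0 to the vector) with Ward linkage.
#'
#' @param x A \linkS4class{LocusExpression}.
#' @return An \code{hclust} object over samples.
#' @export
clusterSamples <- function(x) {
    if (ncol(x) < 2) stop("need at least 2 samples to cluster")
    m <- senseFPKM(x)
    m[is.na(m)] <- 0
    hclust(dist(t(m), method = "euclidean"), method = "ward.D")
}

#' Hierarchical clustering of loci by co-expression across samples
#'
#' Distance between two loci is the reciprocal of the mean product of
#' their sense FPKM over the samples where both are present. Loci with no
#' detectable expression (at the stored FPKM threshold) in any sample are
#' excluded first. Pairs of loci present in no common sample receive a
#' neutral distance equal to the mean of all computable pairwise
#' distances; pairs with shared samples but an all-zero FPKM product would
#' be infinitely distant and are capped at the maximum finite distance.
#' Ward linkage.
#'
#' @param x A \linkS4class{LocusExpression}.
#' @return An \code{hclust} object over the retained loci.
#' @export
clusterLoci <- function(x) {
    ex <- isExpressed(x)
    keep <- apply(ex, 1L, function(r) any(r, na.rm = TRUE))
    if (sum(keep) < 2)
        stop("need at least 2 loci with detectable expression")
    s <- senseFPKM(x)[keep, , drop = FALSE]
    p <- isPresent(x)[keep, , drop = FALSE]
    n <- nrow(s)
    D <- matrix(NA_real_, n, n, dimnames = list(rownames(s), rownames(s)))
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        shared <- p[i, ] & p[j, ]
        if (!any(shared)) next
        m <- mean(s[i, shared] * s[j, shared])
        D[i, j] <- D[j, i] <- if (m == 0) Inf else 1 / m
    }
    finite <- D[is.finite(D)]
    if (length(finite) == 0) stop("no computable pairwise distance")
    D[is.infinite(D)] <- max(finite)
    D[is.na(D)] <- mean(finite)
    diag(D) <- 0
    hclust(stats::as.dist(D), method = "ward.D")
}

#' Export a dendrogram in Newick format
#'
#' @param hc An \code{hclust} object.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
writeNewick <- function(hc, path) {
    ape::write.tree(ape::as.phylo(hc), file = path)
    invisible(path)
}
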