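#' Detect 3' transductions from soft-clipped split reads
#'
#' Transcriptional readthrough past the weak L1 poly(A) signal co-mobilizes
#' unique sequence downstream of a source element, so junction reads of a
#' daughter (progeny) insertion can carry a clipped tail that maps
#' downstream-adjacent to the progenitor. Split reads are kept when both
#' segments map with MAPQ strictly greater than \code{mapq_min}; the
#' primary segment must fall within \code{window} bp of a call's 3' cluster
#' (the progeny) and the clipped segment within \code{window} bp downstream
#' (in the progenitor's sense direction, on the matching strand) of a
#' \emph{different} full-length call (the progenitor). Progenies matching
#' more than one potential progenitor are eliminated entirely.
#'
#' @param split_reads GRanges of primary segments with mcols \code{read_id},
#'   \code{mapq} and clip fields \code{clip_chrom}, \code{clip_start},
#'   \code{clip_end}, \code{clip_strand}, \code{clip_mapq}.
#' @param calls GRanges of 3' calls (with cluster span and
#'   \code{full_length} columns).
#' @param window Adjacency window in bp.
#' @param mapq_min Exclusive MAPQ lower bound for both segments.
#' @return data.frame of transduction events: \code{progeny_call_id},
#'   \code{progenitor_call_id}, \code{n_support_reads} and the transduced
#'   span (\code{chrom}, \code{start}, \code{end}).
#' @export
detectTransductions <- function(split_reads, calls, window = 500,
                                mapq_min = 15) {
    empty <- data.frame(progeny_call_id = character(),
                        progenitor_call_id = character(),
                        n_support_reads = integer(),
                        chrom = character(), start = integer(),
                        end = integer(), stringsAsFactors = FALSE)
    mc <- mcols(split_reads)
    has_clip <- !is.na(mc$clip_start)
    keep <- has_clip & mc$mapq > mapq_min & mc$clip_mapq > mapq_min
    split_reads <- split_reads[keep]
    if (length(split_reads) == 0 || length(calls) == 0) return(empty)
    mc <- mcols(split_reads)
    cmc <- mcols(calls)
    spans <- GRanges(seqnames(calls),
                     IRanges(cmc$cluster_start, cmc$cluster_end))
    # progeny: nearest call whose 3' cluster is within the window
    hit <- distanceToNearest(split_reads, spans, ignore.strand = TRUE)
    prog_idx <- rep(NA_integer_, length(split_reads))
    ok <- mcols(hit)$distance <= window
    prog_idx[queryHits(hit)[ok]] <- subjectHits(hit)[ok]
    # progenitor: full-length call with the clip downstream-adjacent
    clip <- GRanges(mc$clip_chrom, IRanges(mc$clip_start, mc$clip_end),
                    strand = mc$clip_strand)
    fl <- which(cmc$full_length)
    rows <- list()
    for (k in seq_along(split_reads)) {
        gi <- prog_idx[k]
        if (is.na(gi)) next
        for (pi in fl) {
            if (pi == gi) next
            if (as.character(seqnames(clip))[k] !=
                as.character(seqnames(calls))[pi]) next
            ori <- as.character(strand(calls))[pi]
            if (as.character(strand(clip))[k] != ori) next
            p3 <- start(calls)[pi]
            ok <- if (ori == "+")
                start(clip)[k] >= p3 && start(clip)[k] <= p3 + window
            else
                end(clip)[k] <= p3 && end(clip)[k] >= p3 - window
            if (ok)
                rows[[length(rows) + 1L]] <- data.frame(
                    read = k, progeny = gi, progenitor = pi)
        }
    }
    if (length(rows) == 0) return(empty)
    links <- do.call(rbind, rows)
    # progenies with multiple potential progenitors are eliminated
    # (a single read matching two progenitors triggers this too)
    nprog <- tapply(links$progenitor, links$progeny,
                    function(x) length(unique(x)))
    bad <- as.integer(names(nprog)[nprog > 1])
    links <- links[!(links$progeny %in% bad), , drop = FALSE]
    if (nrow(links) == 0) return(empty)
    out <- do.call(rbind, lapply(
        split(links, paste(links$progeny, links$progenitor)),
        function(df) {
            ks <- df$read
            data.frame(
                progeny_call_id = cmc$call_id[df$progeny[1]],
                progenitor_call_id = cmc$call_id[df$progenitor[1]],
                n_support_reads = nrow(df),
                chrom = as.character(seqnames(clip))[ks[1]],
                start = min(start(clip)[ks]),
                end = max(end(clip)[ks]),
                stringsAsFactors = FALSE)
        }))
    rownames(out) <- NULL
    out[order(out$progeny_call_id, out$progenitor_call_id), , drop = FALSE]
}

# does `seq` contain `tag` (full occurrence anywhere, or a partial
# occurrence of at least min_overlap bases at either read end), on either
# strand, within floor(error_rate * matched length) errors?
has_lineage_tag <- function(seq, tag, error_rate, min_overlap) {
    for (s in c(seq, revcomp(seq))) {
        if (!is.null(findAdapter(s, tag, error_rate, min_overlap,
                                 "three_prime")))
            return(TRUE)
        if (!is.null(findAdapter(s, tag, error_rate, min_overlap,
                                 "five_prime")))
            return(TRUE)
    }
    FALSE
}

#' Assign full-length insertions to known hot-L1 lineages
#'
#' Reads are serially searched for lineage-specific transduction tags
#' (error-tolerant, detection only, both strands). Tagged reads whose
#' primary flank alignment has MAPQ strictly above \code{mapq_min} and
#' intersects (or abuts) the 3' cluster span of a full-length call are
#' attributed to that call, except when the alignment falls near an
#' annotated older-subfamily reference element, which is discarded as a
#' false-positive source. A call with at least one surviving supporting
#' read is annotated with that lineage; conflicting lineages for one call
#' are all reported with their read counts.
#'
#' @param reads data.frame with \code{id} and \code{seq}: junction reads
#'   with barcode and linker removed but poly(A)/L1/flank retained (tags
#'   may span homopolymer-rich trimming boundaries, so searching the
#'   untrimmed junction side is deliberate).
#' @param alignments GRanges of the reads' mapped flanks (mcols
#'   \code{read_id}, \code{mapq}, \code{is_secondary}).
#' @param calls GRanges of calls with \code{full_length} and cluster span
#'   columns.
#' @param tags Named character vector of tag sequences
#'   (default \code{\link{lineageTags}}).
#' @param old_catalog Optional GRanges of older-subfamily elements.
#' @param config An \linkS4class{AtlasConfig}.
#' @return List with \code{assignments} (data.frame \code{call_id},
#'   \code{lineage}, \code{n_reads}) and \code{calls} (input calls with a
#'   \code{lineage} column, \code{NA} when unassigned; conflicts joined
#'   with \code{","} by decreasing read count).
#' @export
assignLineages <- function(reads, alignments, calls, tags = lineageTags(),
                           old_catalog = NULL, config = atlasConfig()) {
    stopifnot(is.data.frame(reads), all(c("id", "seq") %in% names(reads)))
    tag_hits <- lapply(names(tags), function(nm) {
        hit <- vapply(reads$seq, has_lineage_tag, logical(1),
                      tag = tags[[nm]],
                      error_rate = config@lineage_error_rate,
                      min_overlap = config@lineage_min_overlap,
                      USE.NAMES = FALSE)
        reads$id[hit]
    })
    names(tag_hits) <- names(tags)
    mcols(calls)$lineage <- rep(NA_character_, length(calls))
    empty <- data.frame(call_id = character(), lineage = character(),
                        n_reads = integer(), stringsAsFactors = FALSE)
    if (all(lengths(tag_hits) == 0))
        return(list(assignments = empty, calls = calls))
    aln <- alignments[!mcols(alignments)$is_secondary &
                      mcols(alignments)$mapq > config@mapq_min_split]
    if (!is.null(old_catalog) && length(old_catalog) > 0) {
        d <- .nearest_distance(aln, old_catalog)
        aln <- aln[d > config@known_insertion_window]
    }
    cmc <- mcols(calls)
    fl <- which(cmc$full_length)
    spans <- GRanges(seqnames(calls)[fl],
                     IRanges(cmc$cluster_start[fl], cmc$cluster_end[fl]))
    rows <- list()
    for (nm in names(tag_hits)) {
        sub <- aln[mcols(aln)$read_id %in% tag_hits[[nm]]]
        if (length(sub) == 0) next
        ov <- findOverlaps(sub, spans, ignore.strand = TRUE, maxgap = 0L)
        if (length(ov) == 0) next
        cnt <- table(subjectHits(ov))
        rows[[nm]] <- data.frame(
            call_id = cmc$call_id[fl][as.integer(names(cnt))],
            lineage = nm, n_reads = as.integer(cnt),
            stringsAsFactors = FALSE)
    }
    if (length(rows) == 0)
        return(list(assignments = empty, calls = calls))
    assignments <- do.call(rbind, rows)
    rownames(assignments) <- NULL
    for (cid in unique(assignments$call_id)) {
        sub <- assignments[assignments$call_id == cid, , drop = FALSE]
        sub <- sub[order(-sub$n_reads, sub$lineage), , drop = FALSE]
        mcols(calls)$lineage[cmc$call_id == cid] <-
            paste(sub$lineage, collapse = ",")
    }
    list(assignments = assignments, calls = calls)
}
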