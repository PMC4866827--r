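#' Support filter for putative insertions
#'
#' A putative insertion is supported when it has at least
#' \code{support_min_3p_reads} non-redundant 3' reads of which at least one
#' ends within a poly(A) tract and/or an L1 sequence, or when it has at
#' least one 5'- and one 3'-ATLAS non-redundant read.
#'
#' @param calls GRanges of 3' calls carrying \code{n_nonredundant},
#'   \code{n_polyA_or_l1} and \code{n_nonredundant_5p} columns.
#' @param config An \linkS4class{AtlasConfig}.
#' @return \code{calls} with a logical \code{support_pass} column.
#' @export
applySupportFilter <- function(calls, config = atlasConfig()) {
    mc <- mcols(calls)
    n5 <- if (!is.null(mc$n_nonredundant_5p)) mc$n_nonredundant_5p else 0L
    mcols(calls)$support_pass <-
        (mc$n_nonredundant >= config@support_min_3p_reads &
             mc$n_polyA_or_l1 >= 1L) |
        (n5 >= 1L & mc$n_nonredundant >= 1L)
    calls
}

#' Map partial primer matches across a genome
#'
#' Spurious priming of the L1-anchored 3' primer at genomic sites that
#' resemble its 3' end is a significant false-positive source. This builds
#' the filter's substrate: every exact genomic occurrence (both strands) of
#' every primer suffix from \code{min_suffix} nt up to the full primer
#' minus one, plus occurrences of the full primer with up to
#' \code{full_mismatches} substitutions. When several primer forms match at
#' the same priming position (same chromosome, strand and primer 3'-end
#' coordinate) only the longest is kept.
#'
#' @param genome A \code{DNAStringSet} (or named character vector) of
#'   chromosome sequences.
#' @param primer Primer sequence.
#' @param min_suffix Shortest suffix length mapped.
#' @param full_mismatches Substitutions allowed on the full primer.
#' @return GRanges of primer sites with a \code{suffix_length} column.
#' @export
buildPrimerSiteMap <- function(genome, primer, min_suffix = 8,
                               full_mismatches = 2) {
    if (!is(genome, "DNAStringSet"))
        genome <- Biostrings::DNAStringSet(genome)
    m <- nchar(primer)
    if (m <= min_suffix) stop("primer must be longer than min_suffix")
    hits <- list()
    scan_one <- function(pat, L, max_mm) {
        pat_f <- Biostrings::DNAString(pat)
        pat_r <- Biostrings::reverseComplement(pat_f)
        for (chr in names(genome)) {
            fwd <- Biostrings::matchPattern(pat_f, genome[[chr]],
                                            max.mismatch = max_mm,
                                            with.indels = FALSE)
            if (length(fwd))
                hits[[length(hits) + 1L]] <<- GRanges(chr,
                    IRanges(start(fwd), end(fwd)), strand = "+",
                    suffix_length = L)
            rev <- Biostrings::matchPattern(pat_r, genome[[chr]],
                                            max.mismatch = max_mm,
                                            with.indels = FALSE)
            if (length(rev))
                hits[[length(hits) + 1L]] <<- GRanges(chr,
                    IRanges(start(rev), end(rev)), strand = "-",
                    suffix_length = L)
        }
    }
    for (L in seq(min_suffix, m - 1L))
        scan_one(substr(primer, m - L + 1L, m), L, 0L)
    scan_one(primer, m, full_mismatches)
    if (length(hits) == 0)
        return(GRanges(suffix_length = integer()))
    gr <- sort(do.call(c, hits), ignore.strand = TRUE)
    # the priming position is the primer 3' end: match end on +, start on -
    prime_pos <- ifelse(as.character(strand(gr)) == "+", end(gr), start(gr))
    key <- paste(seqnames(gr), strand(gr), prime_pos, sep = "\r")
    keep <- vapply(split(seq_along(gr), key), function(ii)
        ii[which.max(mcols(gr)$suffix_length[ii])], integer(1))
    sort(gr[keep], ignore.strand = TRUE)
}

#' Flag primer-artifact calls
#'
#' A putative insertion is a primer artifact when (i) it is not a reference
#' insertion, (ii) a genomic primer site from the
#' \code{\link{buildPrimerSiteMap}} map lies within (or within
#' \code{site_gap} bp of) its 3' cluster span, and (iii) at least one
#' supporting read consists of genomic flank immediately followed by the
#' primer sequence with no L1 or poly(A) sequence in between.
#'
#' @param calls Annotated GRanges of 3' calls (needs \code{is_reference},
#'   cluster span and \code{n_primer_only} columns).
#' @param site_map GRanges from \code{\link{buildPrimerSiteMap}}.
#' @param site_gap Extension of the cluster span when intersecting the site
#'   map; poly(A) trimming can shave a genomic A-run between flank and
#'   primer site, so strict containment is too brittle.
#' @return \code{calls} with a logical \code{primer_artifact} column.
#' @export
applyPrimerArtifactFilter <- function(calls, site_map, site_gap = 100) {
    mc <- mcols(calls)
    if (length(calls) == 0) {
        mcols(calls)$primer_artifact <- logical()
        return(calls)
    }
    span <- GRanges(seqnames(calls),
                    IRanges(pmax(1L, mc$cluster_start - site_gap),
                            mc$cluster_end + site_gap))
    has_site <- overlapsAny(span, site_map, ignore.strand = TRUE)
    mcols(calls)$primer_artifact <-
        !mc$is_reference & has_site & mc$n_primer_only >= 1L
    calls
}

#' Flag insertions attributable to older L1 subfamilies
#'
#' The targeted 3' primer can occasionally amplify older-subfamily elements
#' (clusters typically supported by about ten-fold fewer reads than true
#' young-subfamily insertions). Calls whose insertion point falls within
#' \code{window} bp of an annotated older-subfamily element 3' end are
#' flagged; the read-support ratio of each call against the median support
#' of unflagged calls is reported as a diagnostic, not used as a rule.
#'
#' @param calls GRanges of 3' calls.
#' @param old_catalog GRanges of older-subfamily element 3' ends.
#' @param window Matching window in bp.
#' @return \code{calls} with logical \code{preta} and numeric
#'   \code{preta_support_ratio} columns.
#' @export
applyPretaFilter <- function(calls, old_catalog, window = 200) {
    d <- .nearest_distance(calls, old_catalog)
    flag <- d <= window
    med <- median(mcols(calls)$n_nonredundant[!flag])
    mcols(calls)$preta <- flag
    mcols(calls)$preta_support_ratio <-
        if (is.na(med) || med == 0) rep(NA_real_, length(calls))
        else mcols(calls)$n_nonredundant / med
    calls
}

#' Apply the full filtering tier
#'
#' Runs the support, primer-artifact and older-subfamily filters (the
#' verdicts are independent, so order does not matter) and marks a call as
#' retained when it passes support and is flagged by neither artifact
#' filter.
#'
#' @param calls Annotated GRanges of 3' calls.
#' @param site_map GRanges from \code{\link{buildPrimerSiteMap}}.
#' @param old_catalog GRanges of older-subfamily element 3' ends.
#' @param config An \linkS4class{AtlasConfig}.
#' @return \code{calls} with \code{support_pass}, \code{primer_artifact},
#'   \code{preta} and \code{retained} columns.
#' @export
applyAllFilters <- function(calls, site_map, old_catalog,
                            config = atlasConfig()) {
    calls <- applySupportFilter(calls, config)
    calls <- applyPrimerArtifactFilter(calls, site_map,
                                       site_gap = config@cluster_merge_gap)
    calls <- applyPretaFilter(calls, old_catalog,
                              window = config@known_insertion_window)
    mc <- mcols(calls)
    mcols(calls)$retained <- mc$support_pass & !mc$primer_artifact & !mc$preta
    calls
}

#' In-silico discovery rate against a fixed reference set
#'
#' Fraction of a reference set of population-fixed insertions that have at
#' least one (by default retained) call within \code{window} bp.
#'
#' @param calls GRanges of calls (with a \code{retained} column when
#'   \code{retained_only}).
#' @param fixed_set GRanges of fixed-insertion 3' ends.
#' @param window Matching window in bp.
#' @param retained_only Use only retained calls.
#' @return List with \code{rate} (fraction recovered), \code{n_recovered},
#'   \code{n_fixed} and \code{missed} (the unrecovered subset of
#'   \code{fixed_set}).
#' @export
discoveryRate <- function(calls, fixed_set, window = 200,
                          retained_only = TRUE) {
    if (length(fixed_set) == 0) stop("fixed_set must be non-empty")
    if (retained_only) {
        if (is.null(mcols(calls)$retained))
            stop("calls lack a 'retained' column; run applyAllFilters first")
        calls <- calls[mcols(calls)$retained]
    }
    d <- .nearest_distance(fixed_set, calls)
    found <- d <= window
    list(rate = mean(found), n_recovered = sum(found),
         n_fixed = length(fixed_set), missed = fixed_set[!found])
}
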