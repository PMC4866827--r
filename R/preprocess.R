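#' Locate an adapter or feature sequence in a read
#'
#' Error-tolerant semi-global alignment in the style of cutadapt.
#' Substitutions and indels both count as errors, and the error budget is
#' \code{floor(error_rate * L)} where \code{L} is the length of the adapter
#' portion aligned. With \code{anchor = "anywhere"} only full occurrences of
#' the adapter are admissible. With \code{anchor = "three_prime"} the adapter
#' may additionally occur partially at the read 3' end (a prefix of the
#' adapter, at least \code{min_overlap} long, aligned to the read suffix);
#' \code{anchor = "five_prime"} is the mirror (an adapter suffix at the read
#' start). Among admissible occurrences the one with fewest errors wins,
#' ties broken by the longest matched adapter portion, then by the leftmost
#' start (rightmost for \code{"three_prime"}).
#'
#' @param seq Read sequence (single character string).
#' @param adapter Adapter/feature sequence.
#' @param error_rate Fractional error budget per matched adapter base.
#' @param min_overlap Minimum matched adapter length.
#' @param anchor One of \code{"anywhere"}, \code{"five_prime"},
#'   \code{"three_prime"}.
#' @return \code{NULL} when there is no admissible occurrence; otherwise a
#'   list with \code{start}, \code{end} (1-based read coordinates of the
#'   aligned segment), \code{n_errors} and \code{matched_len}.
#' @export
#' @examples
#' findAdapter("CCCCACGTACGTCCCC", "ACGTACGT", 0.1, 4, "anywhere")
findAdapter <- function(seq, adapter, error_rate = 0.12, min_overlap = 8,
                        anchor = c("anywhere", "five_prime", "three_prime")) {
    anchor <- match.arg(anchor)
    if (nchar(adapter) == 0) stop("adapter must be non-empty")
    if (nchar(seq) == 0) return(NULL)
    if (anchor == "five_prime") {
        r <- cpp_adapter_align(reverse_str(seq), reverse_str(adapter),
                               error_rate, as.integer(min_overlap),
                               TRUE, TRUE)
        if (is.na(r[1])) return(NULL)
        n <- nchar(seq)
        return(list(start = n - r[2] + 1L, end = n - r[1] + 1L,
                    n_errors = r[3], matched_len = r[4]))
    }
    r <- cpp_adapter_align(seq, adapter, error_rate,
                           as.integer(min_overlap),
                           allow_partial = (anchor == "three_prime"),
                           prefer_right = (anchor == "three_prime"))
    if (is.na(r[1])) return(NULL)
    list(start = r[1], end = r[2], n_errors = r[3], matched_len = r[4])
}

reverse_str <- function(x) intToUtf8(rev(utf8ToInt(x)))

#' Demultiplex raw reads by exact 5' barcode match
#'
#' Barcodes are matched as exact prefixes (no errors tolerated) and removed.
#' Reads with no matching barcode are counted as unassigned and dropped;
#' assigned reads shorter than \code{min_read_len} after barcode removal are
#' dropped as too short.
#'
#' @param reads data.frame with columns \code{id}, \code{seq} and optionally
#'   \code{qual} (phred+33 string, same length as \code{seq}).
#' @param barcodes Named character vector, sample label -> barcode sequence.
#' @param config An \linkS4class{AtlasConfig}.
#' @return List with \code{reads} (the input rows assigned to a sample, with
#'   barcode stripped and a \code{sample} column), \code{unassigned} and
#'   \code{too_short} counts.
#' @export
demultiplexReads <- function(reads, barcodes, config = atlasConfig()) {
    stopifnot(is.data.frame(reads), all(c("id", "seq") %in% names(reads)))
    if (anyDuplicated(barcodes))
        stop("duplicate barcode sequences in the barcode map")
    if (is.null(names(barcodes)) || any(!nzchar(names(barcodes))))
        stop("barcodes must be a named vector (sample -> sequence)")
    nb <- nchar(barcodes)
    hit <- rep(NA_integer_, nrow(reads))
    for (k in seq_along(barcodes)) {
        m <- is.na(hit) & substr(reads$seq, 1L, nb[k]) == barcodes[k]
        hit[m] <- k
    }
    unassigned <- sum(is.na(hit))
    out <- reads[!is.na(hit), , drop = FALSE]
    kidx <- hit[!is.na(hit)]
    out$sample <- names(barcodes)[kidx]
    out$seq <- substr(out$seq, nb[kidx] + 1L, nchar(out$seq))
    if (!is.null(out$qual))
        out$qual <- substr(out$qual, nb[kidx] + 1L, nchar(out$qual))
    keep <- nchar(out$seq) >= config@min_read_len
    list(reads = out[keep, , drop = FALSE],
         unassigned = unassigned,
         too_short = sum(!keep))
}

#' Quality-trim the 3' end of a read
#'
#' Standard running-sum rule: the removed suffix is the one maximizing the
#' sum of \code{threshold - q} over its bases; when no suffix has a positive
#' sum the read is returned unchanged.
#'
#' @param seq,qual Sequence and phred+33 quality strings of equal length.
#' @param threshold Phred threshold.
#' @return List with trimmed \code{seq} and \code{qual}.
#' @export
trimQuality3p <- function(seq, qual, threshold = 12) {
    n <- nchar(seq)
    if (n == 0) return(list(seq = seq, qual = qual))
    q <- utf8ToInt(qual) - 33L
    if (length(q) != n) stop("sequence and quality lengths differ")
    d <- threshold - q
    # suffix_sum[k] = sum(d[k:n]); cut at the k maximizing it, if positive
    suffix_sum <- rev(cumsum(rev(d)))
    best <- which.max(suffix_sum)
    if (suffix_sum[best] <= 0) return(list(seq = seq, qual = qual))
    # ties: which.max takes the first (longest removed suffix); prefer the
    # shortest removal instead, i.e. the last k attaining the maximum
    best <- max(which(suffix_sum == suffix_sum[best]))
    list(seq = substr(seq, 1L, best - 1L), qual = substr(qual, 1L, best - 1L))
}

# internal: one iterative 3'-feature trimming pass over (primer, L1 end,
# polyA), repeated until a full pass removes nothing.
trim_features_3p <- function(seq, qual, refs, config) {
    flags <- c(primer = FALSE, l1_end = FALSE, polyA = FALSE)
    feats <- list(
        primer = list(seq = refs[["primer"]],
                      overlap = config@min_adapter_overlap),
        l1_end = list(seq = refs[["l1_end"]],
                      overlap = config@min_adapter_overlap),
        polyA  = list(seq = strrep("A", 100L), overlap = 3L))
    repeat {
        found <- FALSE
        for (nm in names(feats)) {
            if (nchar(seq) == 0) break
            m <- findAdapter(seq, feats[[nm]]$seq,
                             config@adapter_error_rate,
                             feats[[nm]]$overlap, "three_prime")
            if (!is.null(m)) {
                seq <- substr(seq, 1L, m$start - 1L)
                qual <- substr(qual, 1L, m$start - 1L)
                flags[nm] <- TRUE
                found <- TRUE
            }
        }
        if (!found || nchar(seq) == 0) break
    }
    list(seq = seq, qual = qual, flags = flags)
}

trim_result_row <- function(id, sample, side, flank, original_len,
                            flags, reason) {
    data.frame(id = id, sample = sample, side = side,
               flank = flank, original_len = original_len,
               linker = flags[["linker"]], primer = flags[["primer"]],
               l1_end = flags[["l1_end"]], polyA = flags[["polyA"]],
               reason = reason, stringsAsFactors = FALSE)
}

#' Trim 3'-ATLAS reads down to their genomic flank
#'
#' Implements the 3'-library read grammar: the suppression-PCR linker is
#' located (error-tolerantly) at the 5' end and removed -- reads without a
#' linker are rejected -- then the 3' end is quality-trimmed and the
#' L1-anchored primer, the L1 3'-end sequence and a poly(A) stretch are
#' iteratively searched and removed from the 3' end, recording which
#' features were seen. Reads with no detectable 3' feature are kept (they
#' usually did not reach the L1 junction); reads whose flank falls below
#' \code{min_read_len} are rejected.
#'
#' @param reads Demultiplexed reads: data.frame with \code{id}, \code{seq},
#'   optionally \code{qual} and \code{sample}.
#' @param refs Named character vector/list with elements \code{linker},
#'   \code{primer} (the 3' primer) and \code{l1_end} (L1 3'-end sequence);
#'   see \code{\link{atlasAdapters}}.
#' @param config An \linkS4class{AtlasConfig}.
#' @return data.frame with one row per input read: \code{id}, \code{sample},
#'   \code{side}, \code{flank} (NA for rejected reads), \code{original_len},
#'   feature flags \code{linker}/\code{primer}/\code{l1_end}/\code{polyA}
#'   and \code{reason} (\code{NA} = kept, else \code{"no_linker"} or
#'   \code{"too_short"}).
#' @export
trimThreePrimeReads <- function(reads, refs = NULL, config = atlasConfig()) {
    if (is.null(refs)) {
        ad <- atlasAdapters()
        refs <- c(linker = ad[["linker"]], primer = ad[["primer_3p"]],
                  l1_end = ad[["l1_3p_end"]])
    }
    refs <- as.list(refs)
    n <- nrow(reads)
    sample <- if (!is.null(reads$sample)) reads$sample else
        rep(NA_character_, n)
    qual <- if (!is.null(reads$qual)) reads$qual else
        strrep("I", nchar(reads$seq))
    out <- vector("list", n)
    for (i in seq_len(n)) {
        s <- reads$seq[i]; q <- qual[i]
        olen <- nchar(s)
        flags <- c(linker = FALSE, primer = FALSE, l1_end = FALSE,
                   polyA = FALSE)
        m <- findAdapter(s, refs$linker, config@adapter_error_rate,
                         config@min_adapter_overlap, "five_prime")
        if (is.null(m)) {
            out[[i]] <- trim_result_row(reads$id[i], sample[i],
                "three_prime", NA_character_, olen, flags, "no_linker")
            next
        }
        flags["linker"] <- TRUE
        s <- substr(s, m$end + 1L, nchar(s))
        q <- substr(q, m$end + 1L, nchar(q))
        if (nchar(s) < config@min_read_len) {
            out[[i]] <- trim_result_row(reads$id[i], sample[i],
                "three_prime", NA_character_, olen, flags, "too_short")
            next
        }
        tq <- trimQuality3p(s, q, config@quality_trim_threshold)
        ft <- trim_features_3p(tq$seq, tq$qual, refs, config)
        flags[names(ft$flags)] <- ft$flags
        if (nchar(ft$seq) < config@min_read_len) {
            out[[i]] <- trim_result_row(reads$id[i], sample[i],
                "three_prime", NA_character_, olen, flags, "too_short")
        } else {
            out[[i]] <- trim_result_row(reads$id[i], sample[i],
                "three_prime", ft$seq, olen, flags, NA_character_)
        }
    }
    do.call(rbind, out)
}

#' Trim 5'-ATLAS reads down to their genomic flank
#'
#' Implements the 5'-library read grammar. Reads shorter than
#' \code{min_5prime_read_len} did not reach the junction and are rejected
#' outright. The 5'-anchored primer and then the L1 5'-end sequence are
#' removed from the read 5' end, and the linker from the 3' end; a read
#' missing any of these features is rejected. The remaining flank is
#' reverse-complemented so that, like 3' flanks, it reads from the linker
#' position toward the L1 element.
#'
#' @inheritParams trimThreePrimeReads
#' @param refs Named vector/list with \code{linker}, \code{primer} (the 5'
#'   primer) and \code{l1_end} (L1 5'-end sequence).
#' @return data.frame as in \code{\link{trimThreePrimeReads}} with
#'   \code{side = "five_prime"}; rejection reasons are
#'   \code{"too_short_raw"}, \code{"missing_feature"} and \code{"too_short"}.
#' @export
trimFivePrimeReads <- function(reads, refs = NULL, config = atlasConfig()) {
    if (is.null(refs)) {
        ad <- atlasAdapters()
        refs <- c(linker = ad[["linker"]], primer = ad[["primer_5p"]],
                  l1_end = ad[["l1_5p_end"]])
    }
    refs <- as.list(refs)
    n <- nrow(reads)
    sample <- if (!is.null(reads$sample)) reads$sample else
        rep(NA_character_, n)
    qual <- if (!is.null(reads$qual)) reads$qual else
        strrep("I", nchar(reads$seq))
    out <- vector("list", n)
    for (i in seq_len(n)) {
        s <- reads$seq[i]; q <- qual[i]
        olen <- nchar(s)
        flags <- c(linker = FALSE, primer = FALSE, l1_end = FALSE,
                   polyA = FALSE)
        row <- function(flank, reason)
            trim_result_row(reads$id[i], sample[i], "five_prime", flank,
                            olen, flags, reason)
        if (olen < config@min_5prime_read_len) {
            out[[i]] <- row(NA_character_, "too_short_raw"); next
        }
        tq <- trimQuality3p(s, q, config@quality_trim_threshold)
        s <- tq$seq; q <- tq$qual
        m <- findAdapter(s, refs$primer, config@adapter_error_rate,
                         config@min_adapter_overlap, "five_prime")
        if (is.null(m)) { out[[i]] <- row(NA_character_, "missing_feature"); next }
        flags["primer"] <- TRUE
        s <- substr(s, m$end + 1L, nchar(s)); q <- substr(q, m$end + 1L, nchar(q))
        m <- findAdapter(s, refs$l1_end, config@adapter_error_rate,
                         config@min_adapter_overlap, "five_prime")
        if (is.null(m)) { out[[i]] <- row(NA_character_, "missing_feature"); next }
        flags["l1_end"] <- TRUE
        s <- substr(s, m$end + 1L, nchar(s)); q <- substr(q, m$end + 1L, nchar(q))
        m <- findAdapter(s, refs$linker, config@adapter_error_rate,
                         config@min_adapter_overlap, "three_prime")
        if (is.null(m)) { out[[i]] <- row(NA_character_, "missing_feature"); next }
        flags["linker"] <- TRUE
        s <- substr(s, 1L, m$start - 1L)
        if (nchar(s) < config@min_read_len) {
            out[[i]] <- row(NA_character_, "too_short"); next
        }
        out[[i]] <- row(revcomp(s), NA_character_)
    }
    do.call(rbind, out)
}
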