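#' Run the full insertion-calling pipeline on an experiment bundle
#'
#' Executes the end-to-end chain on in-memory inputs of the shape produced
#' by \code{\link{simulateAtlasExperiment}} (or assembled from files with
#' the package readers): demultiplex, trim both libraries, join trimming
#' features onto the flank alignments, MAPQ/secondary filtering,
#' linker-position deduplication, strand-aware clustering, insertion-point
#' calling, 5'/3' pairing, catalog annotation, primer-site-map
#' construction, the three-filter tier, split-read transduction detection
#' and lineage-tag assignment. Per-stage record counts are collected in a
#' manifest.
#'
#' @param sim List with \code{reads_3p}, \code{reads_5p},
#'   \code{alignments}, \code{barcodes}, \code{refs}, \code{catalogs} and
#'   \code{genome} (see \code{\link{simulateAtlasExperiment}}).
#' @param config An \linkS4class{AtlasConfig}.
#' @param tags Lineage tags (\code{NULL} disables lineage assignment).
#' @return List with \code{calls} (annotated, filtered GRanges),
#'   \code{clusters_3p}, \code{clusters_5p}, \code{transductions},
#'   \code{lineages}, \code{primer_map}, \code{trim_3p}, \code{trim_5p}
#'   and \code{manifest} (named list of per-stage counts and the config
#'   snapshot).
#' @export
runAtlasPipeline <- function(sim, config = atlasConfig(),
                             tags = lineageTags()) {
    refs <- sim$refs
    refs3 <- c(linker = unname(refs[["linker"]]),
               primer = unname(refs[["primer_3p"]]),
               l1_end = unname(refs[["l1_3p_end"]]))
    refs5 <- c(linker = unname(refs[["linker"]]),
               primer = unname(refs[["primer_5p"]]),
               l1_end = unname(refs[["l1_5p_end"]]))
    manifest <- list(config = as.list_config(config))

    dm3 <- demultiplexReads(sim$reads_3p, sim$barcodes, config)
    trim3 <- trimThreePrimeReads(dm3$reads, refs3, config)
    manifest$reads_3p_raw <- nrow(sim$reads_3p)
    manifest$reads_3p_unassigned <- dm3$unassigned
    manifest$reads_3p_trimmed <- sum(is.na(trim3$reason))

    has5 <- !is.null(sim$reads_5p) && nrow(sim$reads_5p) > 0
    trim5 <- NULL
    if (has5) {
        dm5 <- demultiplexReads(sim$reads_5p, sim$barcodes, config)
        trim5 <- trimFivePrimeReads(dm5$reads, refs5, config)
        manifest$reads_5p_raw <- nrow(sim$reads_5p)
        manifest$reads_5p_trimmed <- sum(is.na(trim5$reason))
    }

    aln3 <- joinTrimInfo(sim$alignments, trim3)
    aln3f <- filterAlignments(aln3, config@mapq_min_call)
    nr3 <- deduplicateReads(aln3f)
    clusters3 <- clusterReads(nr3, "three_prime",
                              gap = config@cluster_merge_gap)
    clusters3 <- normalizeCounts(clusters3,
                                 total_redundant = max(1L, length(aln3f)),
                                 total_nonredundant = max(1L, length(nr3)))
    manifest$reads_3p_mapped <- length(aln3f)
    manifest$reads_3p_nonredundant <- length(nr3)
    manifest$clusters_3p <- length(clusters3)

    clusters5 <- NULL
    if (has5) {
        aln5 <- joinTrimInfo(sim$alignments, trim5)
        aln5f <- filterAlignments(aln5, config@mapq_min_call)
        nr5 <- deduplicateReads(aln5f)
        clusters5 <- clusterReads(nr5, "five_prime",
                                  gap = config@cluster_merge_gap)
        manifest$reads_5p_nonredundant <- length(nr5)
        manifest$clusters_5p <- length(clusters5)
    }

    calls <- callInsertionPoints(clusters3)
    calls <- pairFullLength(calls,
                            if (is.null(clusters5))
                                GRanges() else clusters5,
                            window = config@fulllength_pair_window)
    calls <- annotateCalls(calls, sim$catalogs,
                           window = config@known_insertion_window)
    primer_map <- buildPrimerSiteMap(sim$genome, refs3[["primer"]],
                                     min_suffix = config@primer_min_suffix,
                                     full_mismatches =
                                         config@primer_full_mismatches)
    calls <- applyAllFilters(calls, primer_map,
                             sim$catalogs$old_subfamily, config)
    manifest$calls <- length(calls)
    manifest$calls_retained <- sum(mcols(calls)$retained)

    split_reads <- aln3f[!is.na(mcols(aln3f)$clip_start)]
    transductions <- detectTransductions(split_reads, calls,
                                         window = config@transduction_window,
                                         mapq_min = config@mapq_min_split)
    manifest$transduction_events <- nrow(transductions)

    lineages <- NULL
    if (!is.null(tags)) {
        lin_reads <- linker_clipped_reads(dm3$reads, refs3[["linker"]],
                                          config)
        lineages <- assignLineages(lin_reads, aln3f, calls, tags,
                                   old_catalog = sim$catalogs$old_subfamily,
                                   config = config)
        calls <- lineages$calls
        manifest$lineage_assignments <- nrow(lineages$assignments)
    }

    list(calls = calls, clusters_3p = clusters3, clusters_5p = clusters5,
         transductions = transductions, lineages = lineages,
         primer_map = primer_map, trim_3p = trim3, trim_5p = trim5,
         manifest = manifest)
}

# reads with barcode already removed: also strip the linker, keeping
# poly(A)/L1/flank intact for lineage-tag searching
linker_clipped_reads <- function(reads, linker, config) {
    seqs <- vapply(reads$seq, function(s) {
        m <- findAdapter(s, linker, config@adapter_error_rate,
                         config@min_adapter_overlap, "five_prime")
        if (is.null(m)) s else substr(s, m$end + 1L, nchar(s))
    }, character(1), USE.NAMES = FALSE)
    data.frame(id = reads$id, seq = seqs, stringsAsFactors = FALSE)
}

as.list_config <- function(config) {
    out <- lapply(slotNames(config), function(nm) slot(config, nm))
    names(out) <- slotNames(config)
    out
}

#' Compare pipeline calls with simulator ground truth
#'
#' @param result Output of \code{\link{runAtlasPipeline}}.
#' @param sim The simulated experiment the result came from.
#' @param window Matching window in bp (0 demands exact coordinates).
#' @param retained_only Only consider retained calls.
#' @return data.frame per planted insertion: \code{ins_id}, \code{found},
#'   \code{coord_error}, \code{orientation_ok}, \code{full_length_ok}.
#' @export
compareToTruth <- function(result, sim, window = 0,
                           retained_only = TRUE) {
    calls <- result$calls
    if (retained_only) calls <- calls[mcols(calls)$retained]
    truth <- sim$truth
    out <- lapply(seq_len(nrow(truth)), function(i) {
        t <- truth[i, ]
        d <- ifelse(as.character(seqnames(calls)) == t$chrom,
                    abs(start(calls) - t$p3), Inf)
        j <- if (length(d) && any(is.finite(d))) which.min(d) else NA
        found <- !is.na(j) && d[j] <= window
        data.frame(
            ins_id = t$ins_id, found = found,
            coord_error = if (found) as.integer(d[j]) else NA_integer_,
            orientation_ok = if (found)
                as.character(strand(calls))[j] == t$orientation else NA,
            full_length_ok = if (found)
                mcols(calls)$full_length[j] == t$full_length else NA,
            stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}
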