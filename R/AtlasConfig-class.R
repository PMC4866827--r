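#' AtlasConfig: pipeline constants
#'
#' Holds every tunable constant of the insertion-calling and expression
#' pipeline. Defaults are the operating values of the method: cutadapt-style
#' trimming at 12\% error rate with 8-nt minimum adapter overlap and 25-nt
#' minimum read length, Q12 3'-quality trimming, a 133-nt raw-length cutoff
#' for the 5'-ATLAS library, MAPQ gates (> 20 for calling, > 15 for split
#' segments and lineage reads, >= 20 for RNA fragments), 100-bp same-strand
#' cluster merging, a 7-kb 5'/3' pairing window, a 200-bp window for matching
#' known insertions, primer-map parameters (8-nt minimum suffix, 2 mismatches
#' on the full 22-nt primer), the 3-read/1-poly(A)-or-L1 support rule, 1-kb
#' expression flanks with a 0.05 FPKM expressed threshold, consensus
#' diagnostic positions 5927-5929 (1-based), lineage matching at 10\% error
#' with 16-nt minimum overlap, 50-bp profile bins, and the 10-fold
#' read-support ratio reported for older-subfamily carry-over clusters.
#'
#' @slot min_read_len minimum retained flank length (nt)
#' @slot adapter_error_rate error rate for adapter/feature matching
#' @slot min_adapter_overlap minimum adapter overlap (nt)
#' @slot quality_trim_threshold phred threshold for 3' quality trimming
#' @slot min_5prime_read_len minimum raw 5'-ATLAS read length (nt)
#' @slot mapq_min_call reads with MAPQ <= this are removed before calling
#' @slot mapq_min_split split-read segments require MAPQ > this
#' @slot mapq_min_rna RNA fragments require MAPQ >= this
#' @slot cluster_merge_gap maximum same-strand merge distance (bp)
#' @slot fulllength_pair_window 5'/3' pairing window (bp)
#' @slot known_insertion_window window for matching catalogued insertions (bp)
#' @slot primer_min_suffix shortest exact primer suffix mapped genome-wide (nt)
#' @slot primer_full_mismatches mismatches allowed on the full primer
#' @slot support_min_3p_reads minimum non-redundant 3' reads (branch 1)
#' @slot expression_flank flanking window for locus FPKM (bp)
#' @slot expressed_fpkm_threshold FPKM above which a locus is expressed
#' @slot diag_positions 1-based consensus positions of the diagnostic triple
#' @slot lineage_error_rate error rate for lineage-tag matching
#' @slot lineage_min_overlap minimum lineage-tag overlap (nt)
#' @slot profile_bin metaprofile bin width (bp)
#' @slot preta_support_ratio fold difference in support expected for
#'   older-subfamily clusters (diagnostic only)
#' @slot transduction_window adjacency window for split-read transduction
#'   matching (bp)
#' @exportClass AtlasConfig
setClass("AtlasConfig", representation(
    min_read_len = "integer",
    adapter_error_rate = "numeric",
    min_adapter_overlap = "integer",
    quality_trim_threshold = "integer",
    min_5prime_read_len = "integer",
    mapq_min_call = "integer",
    mapq_min_split = "integer",
    mapq_min_rna = "integer",
    cluster_merge_gap = "integer",
    fulllength_pair_window = "integer",
    known_insertion_window = "integer",
    primer_min_suffix = "integer",
    primer_full_mismatches = "integer",
    support_min_3p_reads = "integer",
    expression_flank = "integer",
    expressed_fpkm_threshold = "numeric",
    diag_positions = "integer",
    lineage_error_rate = "numeric",
    lineage_min_overlap = "integer",
    profile_bin = "integer",
    preta_support_ratio = "numeric",
    transduction_window = "integer"
))

setValidity("AtlasConfig", function(object) {
    msg <- character()
    for (nm in slotNames(object)) {
        v <- slot(object, nm)
        if (length(v) == 0 || anyNA(v))
            msg <- c(msg, paste0(nm, ": must be set and non-missing"))
        else if (nm != "diag_positions" && length(v) != 1)
            msg <- c(msg, paste0(nm, ": must be a single value"))
        else if (any(v <= 0) && nm != "diag_positions")
            msg <- c(msg, paste0(nm, ": must be strictly positive"))
    }
    for (nm in c("adapter_error_rate", "lineage_error_rate")) {
        v <- slot(object, nm)
        if (length(v) == 1 && !is.na(v) && (v <= 0 || v >= 1))
            msg <- c(msg, paste0(nm, ": must lie in (0, 1)"))
    }
    dp <- object@diag_positions
    if (length(dp) != 3 || anyNA(dp) || any(dp <= 0) ||
        !all(diff(dp) == 1L))
        msg <- c(msg,
            "diag_positions: must be three contiguous 1-based positions")
    if (length(msg)) msg else TRUE
})

#' Construct and validate an AtlasConfig
#'
#' @param ... named overrides of any \linkS4class{AtlasConfig} slot.
#' @return A validated \linkS4class{AtlasConfig}.
#' @export
#' @examples
#' cfg <- atlasConfig()
#' cfg2 <- atlasConfig(cluster_merge_gap = 50)
atlasConfig <- function(...) {
    defaults <- list(
        min_read_len = 25L,
        adapter_error_rate = 0.12,
        min_adapter_overlap = 8L,
        quality_trim_threshold = 12L,
        min_5prime_read_len = 133L,
        mapq_min_call = 20L,
        mapq_min_split = 15L,
        mapq_min_rna = 20L,
        cluster_merge_gap = 100L,
        fulllength_pair_window = 7000L,
        known_insertion_window = 200L,
        primer_min_suffix = 8L,
        primer_full_mismatches = 2L,
        support_min_3p_reads = 3L,
        expression_flank = 1000L,
        expressed_fpkm_threshold = 0.05,
        diag_positions = 5927:5929,
        lineage_error_rate = 0.1,
        lineage_min_overlap = 16L,
        profile_bin = 50L,
        preta_support_ratio = 10,
        transduction_window = 500L
    )
    ov <- list(...)
    bad <- setdiff(names(ov), names(defaults))
    if (length(bad))
        stop("unknown config field(s): ", paste(bad, collapse = ", "))
    int_slots <- names(defaults)[vapply(defaults, is.integer, logical(1))]
    defaults[names(ov)] <- ov
    for (nm in int_slots)
        if (!anyNA(defaults[[nm]]))
            defaults[[nm]] <- as.integer(defaults[[nm]])
    obj <- do.call(new, c(list("AtlasConfig"), defaults))
    validObject(obj)
    obj
}

#' Read an AtlasConfig from a flat key=value text file
#'
#' Lines of the form \code{field = value} (or \code{field=value}); blank
#' lines and lines starting with \code{#} are ignored. \code{diag_positions}
#' may be given as comma-separated values.
#'
#' @param path Path to the configuration file.
#' @param ... Further overrides applied on top of the file values.
#' @return A validated \linkS4class{AtlasConfig}.
#' @export
readAtlasConfig <- function(path, ...) {
    lines <- trimws(readLines(path))
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    kv <- strsplit(lines, "=", fixed = TRUE)
    if (any(lengths(kv) != 2))
        stop("malformed config line: ", lines[which(lengths(kv) != 2)[1]])
    vals <- lapply(kv, function(p) {
        v <- as.numeric(strsplit(trimws(p[2]), ",")[[1]])
        if (anyNA(v)) stop("non-numeric value for field ", trimws(p[1]))
        v
    })
    names(vals) <- vapply(kv, function(p) trimws(p[1]), character(1))
    ov <- list(...)
    vals[names(ov)] <- ov
    do.call(atlasConfig, vals)
}

#' Write an AtlasConfig to a flat key=value text file
#'
#' @param config An \linkS4class{AtlasConfig}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeAtlasConfig <- function(config, path) {
    stopifnot(is(config, "AtlasConfig"))
    lines <- vapply(slotNames(config), function(nm) {
        paste0(nm, " = ", paste(slot(config, nm), collapse = ","))
    }, character(1))
    writeLines(lines, path)
    invisible(path)
}

setMethod("show", "AtlasConfig", function(object) {
    cat("AtlasConfig with", length(slotNames(object)), "parameters\n")
    for (nm in slotNames(object))
        cat(sprintf("  %-24s %s\n", nm,
                    paste(slot(object, nm), collapse = ",")))
})
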