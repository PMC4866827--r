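# File-format surface: SAM round-trip for flank alignments, BED/JSON-lines
# for calls, FASTA/FASTQ/BED emission of a whole simulated experiment.

#' Write flank alignments as SAM
#'
#' Emits one primary record per mapped flank read (flag 0/16, MAPQ, CIGAR
#' all-matched); split reads carry their clipped-segment location in an
#' \code{SA} tag so the round-trip through \code{\link{readAtlasAlignments}}
#' restores the clip fields.
#'
#' @param alignments GRanges with \code{read_id}, \code{mapq},
#'   \code{is_secondary} and clip fields.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeAtlasSam <- function(alignments, path) {
    sl <- GenomeInfoDb::seqlengths(alignments)
    if (anyNA(sl)) stop("alignments need seqlengths to write SAM")
    hdr <- c("@HD\tVN:1.6\tSO:coordinate",
             sprintf("@SQ\tSN:%s\tLN:%d", names(sl), sl))
    alignments <- sort(alignments, ignore.strand = TRUE)
    mc <- mcols(alignments)
    flag <- ifelse(as.character(strand(alignments)) == "-", 16L, 0L) +
        ifelse(mc$is_secondary, 256L, 0L)
    sa <- rep("", length(alignments))
    has_clip <- !is.na(mc$clip_start)
    sa[has_clip] <- sprintf("\tSA:Z:%s,%d,%s,%dM,%d,0;",
                            mc$clip_chrom[has_clip],
                            mc$clip_start[has_clip],
                            mc$clip_strand[has_clip],
                            mc$clip_end[has_clip] -
                                mc$clip_start[has_clip] + 1L,
                            mc$clip_mapq[has_clip])
    rec <- sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t*\t*%s",
                   mc$read_id, flag, as.character(seqnames(alignments)),
                   start(alignments), mc$mapq, width(alignments), sa)
    writeLines(c(hdr, rec), path)
    invisible(path)
}

#' Read flank alignments from SAM/BAM
#'
#' Parses primary and secondary records into the alignment GRanges used by
#' the caller, extracting the clipped-segment location of split reads from
#' the \code{SA} tag.
#'
#' @param path A SAM or BAM file.
#' @return GRanges with \code{read_id}, \code{mapq}, \code{is_secondary}
#'   and clip fields.
#' @export
readAtlasAlignments <- function(path) {
    bam <- if (grepl("\\.sam$", path, ignore.case = TRUE))
        Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                         indexDestination = FALSE)
    else path
    p <- Rsamtools::ScanBamParam(
        what = c("qname", "flag", "mapq"), tag = "SA",
        flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
    ga <- GenomicAlignments::readGAlignments(bam, param = p)
    gr <- GRanges(seqnames(ga), IRanges(start(ga), end(ga)),
                  strand = strand(ga),
                  seqinfo = GenomeInfoDb::seqinfo(ga))
    sa <- mcols(ga)$SA
    clip_chrom <- rep(NA_character_, length(ga))
    clip_start <- clip_end <- clip_mapq <- rep(NA_integer_, length(ga))
    clip_strand <- rep(NA_character_, length(ga))
    has <- !is.na(sa) & nzchar(sa)
    if (any(has)) {
        parts <- strsplit(sub(";.*$", "", sa[has]), ",", fixed = TRUE)
        bad <- which(lengths(parts) != 6)
        if (length(bad))
            stop("malformed SA tag in record ", which(has)[bad[1]])
        clip_chrom[has] <- vapply(parts, `[`, "", 1L)
        clip_start[has] <- as.integer(vapply(parts, `[`, "", 2L))
        clip_strand[has] <- vapply(parts, `[`, "", 3L)
        mlen <- as.integer(sub("M", "",
                               vapply(parts, `[`, "", 4L), fixed = TRUE))
        clip_end[has] <- clip_start[has] + mlen - 1L
        clip_mapq[has] <- as.integer(vapply(parts, `[`, "", 5L))
    }
    mcols(gr) <- DataFrame(
        read_id = mcols(ga)$qname, mapq = mcols(ga)$mapq,
        is_secondary = bitwAnd(mcols(ga)$flag, 256L) > 0L,
        clip_chrom = clip_chrom, clip_start = clip_start,
        clip_end = clip_end, clip_strand = clip_strand,
        clip_mapq = clip_mapq)
    gr
}

.call_cols <- c("call_id", "side", "cluster_start", "cluster_end",
                "cluster_strand", "n_nonredundant", "n_redundant",
                "n_polyA_or_l1", "n_primer_only", "full_length",
                "pair_distance", "n_nonredundant_5p", "five_prime_call_id",
                "is_reference", "known_status", "gene_context",
                "cnv_state", "support_pass", "primer_artifact", "preta",
                "preta_support_ratio", "retained", "lineage")

#' Write insertion calls to disk
#'
#' \code{"bed"} writes a BED6+ table (0-based half-open insertion point,
#' score = non-redundant 3' support, strand = element orientation, named
#' extra columns) with a header comment; \code{"jsonl"} writes one JSON
#' object per call with the full record. Output ordering is deterministic
#' (chromosome, coordinate, call id).
#'
#' @param calls GRanges of calls.
#' @param path Output path.
#' @param format \code{"bed"} or \code{"jsonl"}.
#' @return The path, invisibly.
#' @export
writeCalls <- function(calls, path, format = c("bed", "jsonl")) {
    format <- match.arg(format)
    o <- order(as.character(seqnames(calls)), start(calls),
               mcols(calls)$call_id)
    calls <- calls[o]
    mc <- mcols(calls)
    cols <- intersect(.call_cols, names(mc))
    df <- cbind(
        data.frame(chrom = as.character(seqnames(calls)),
                   start = start(calls) - 1L, end = start(calls),
                   name = mc$call_id,
                   score = mc$n_nonredundant,
                   strand = as.character(strand(calls)),
                   stringsAsFactors = FALSE),
        as.data.frame(mc[setdiff(cols, "call_id")]))
    if (format == "bed") {
        con <- file(path, "w")
        on.exit(close(con))
        writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
        if (nrow(df))
            write.table(df, con, sep = "\t", quote = FALSE,
                        row.names = FALSE, col.names = FALSE, na = "NA")
    } else {
        writeLines(vapply(seq_len(nrow(df)), function(i)
            as.character(jsonlite::toJSON(as.list(df[i, , drop = FALSE]),
                                          auto_unbox = TRUE, digits = NA,
                                          na = "null")),
            character(1)), path)
    }
    invisible(path)
}

#' Read insertion calls written by writeCalls (BED format)
#'
#' @param path A file produced by \code{writeCalls(..., format = "bed")}.
#' @param seqinfo Optional Seqinfo for the returned GRanges.
#' @return GRanges of calls.
#' @export
readCalls <- function(path, seqinfo = NULL) {
    first <- readLines(path, n = 1L)
    if (!startsWith(first, "#")) stop("missing header line in ", path)
    cols <- strsplit(sub("^#", "", first), "\t", fixed = TRUE)[[1]]
    df <- read.table(path, sep = "\t", col.names = cols,
                     stringsAsFactors = FALSE, na.strings = "NA",
                     comment.char = "#",
                     colClasses = c(chrom = "character"))
    if (nrow(df) == 0)
        return(GRanges())
    gr <- GRanges(df$chrom, IRanges(df$start + 1L, df$end),
                  strand = df$strand)
    if (!is.null(seqinfo)) GenomeInfoDb::seqinfo(gr) <- seqinfo
    rest <- df[, setdiff(cols, c("chrom", "start", "end", "name",
                                 "score", "strand")), drop = FALSE]
    mcols(gr) <- cbind(DataFrame(call_id = df$name,
                                 n_nonredundant = df$score),
                       DataFrame(rest))
    gr
}

#' Write a simulated experiment to standard formats
#'
#' Emits the synthetic genome (FASTA), the raw 3' and 5' read libraries
#' (FASTQ), the true flank alignments (SAM), the annotation catalogs
#' (BED) and the ground truth (JSON) under a directory.
#'
#' @param sim Output of \code{\link{simulateAtlasExperiment}}.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    Biostrings::writeXStringSet(sim$genome, file.path(dir, "genome.fa"))
    wfq <- function(df, path) {
        if (nrow(df) == 0) { file.create(path); return(invisible()) }
        writeLines(as.vector(rbind(paste0("@", df$id), df$seq,
                                   "+", df$qual)), path)
    }
    wfq(sim$reads_3p, file.path(dir, "atlas_3p.fastq"))
    wfq(sim$reads_5p, file.path(dir, "atlas_5p.fastq"))
    writeAtlasSam(sim$alignments, file.path(dir, "alignments.sam"))
    for (nm in names(sim$catalogs)) {
        gr <- sim$catalogs[[nm]]
        nm_col <- if (nm == "cnv") mcols(gr)$state else
            as.character(seq_along(gr))
        mcols(gr) <- NULL
        if (length(gr)) names(gr) <- nm_col
        rtracklayer::export(gr, file.path(dir, paste0(nm, ".bed")),
                            format = "BED")
    }
    writeLines(as.vector(rbind(paste0(">", names(sim$refs)),
                               unname(sim$refs))),
               file.path(dir, "adapters.fa"))
    write.table(data.frame(sample = names(sim$barcodes),
                           barcode = unname(sim$barcodes)),
                file.path(dir, "barcodes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                         dataframe = "rows", na = "null")
    invisible(dir)
}

#' Load an experiment bundle from a directory of standard files
#'
#' Reads back what \code{\link{writeSimulation}} emitted (genome FASTA,
#' FASTQ libraries, SAM alignments, BED catalogs, adapter FASTA and
#' barcode TSV) into the bundle shape consumed by
#' \code{\link{runAtlasPipeline}}.
#'
#' @param dir Directory containing the files.
#' @return List with \code{genome}, \code{reads_3p}, \code{reads_5p},
#'   \code{alignments}, \code{catalogs}, \code{refs} and \code{barcodes}.
#' @export
readSimulation <- function(dir) {
    rfq <- function(path) {
        if (!file.exists(path) || file.size(path) == 0)
            return(data.frame(id = character(), seq = character(),
                              qual = character(),
                              stringsAsFactors = FALSE))
        ln <- readLines(path)
        data.frame(id = sub("^@", "", ln[seq(1, length(ln), 4)]),
                   seq = ln[seq(2, length(ln), 4)],
                   qual = ln[seq(4, length(ln), 4)],
                   stringsAsFactors = FALSE)
    }
    genome <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
    names(genome) <- sub("\\s.*$", "", names(genome))
    cat_files <- list.files(dir, pattern = "\\.bed$", full.names = FALSE)
    catalogs <- lapply(cat_files, function(f) {
        gr <- rtracklayer::import(file.path(dir, f), format = "BED")
        if (identical(sub("\\.bed$", "", f), "cnv"))
            mcols(gr)$state <- mcols(gr)$name
        gr
    })
    names(catalogs) <- sub("\\.bed$", "", cat_files)
    ad <- Biostrings::readDNAStringSet(file.path(dir, "adapters.fa"))
    refs <- structure(as.character(ad), names = names(ad))
    bc <- read.table(file.path(dir, "barcodes.tsv"), header = TRUE,
                     sep = "\t", stringsAsFactors = FALSE)
    list(genome = genome,
         reads_3p = rfq(file.path(dir, "atlas_3p.fastq")),
         reads_5p = rfq(file.path(dir, "atlas_5p.fastq")),
         alignments = readAtlasAlignments(file.path(dir,
                                                    "alignments.sam")),
         catalogs = catalogs,
         refs = refs,
         barcodes = structure(bc$barcode, names = bc$sample))
}
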