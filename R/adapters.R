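#' Synthetic ATLAS-seq feature reference sequences
#'
#' The trimming grammar of an ATLAS-seq read is defined by a small set of
#' feature sequences: the suppression-PCR linker, the two L1-anchored PCR
#' primers (one priming in the L1 3' end for the 3'-ATLAS library, one in the
#' L1 5' UTR for the 5'-ATLAS library) and the terminal portions of the L1
#' element itself that are read through before reaching genomic sequence.
#' These sequences are inputs to the pipeline (FASTA); the set returned here
#' is a synthetic stand-in used by the simulator and the test suite, not the
#' oligonucleotides of any real library design.
#'
#' @return Named character vector with elements \code{linker},
#'   \code{primer_3p} (22 nt, anneals in the L1 3' end), \code{primer_5p}
#'   (22 nt, anneals in the L1 5' UTR), \code{l1_3p_end} and \code{l1_5p_end}
#'   (40 nt each, the element extremities as they appear in reads).
#' @export
#' @examples
#' atlasAdapters()
atlasAdapters <- function() {
    c(linker    = "GTCTGCACGGTCTAGTCGACGGTATCGAGC",
      primer_3p = "GCGATCGTTCGACTGCCTGGAT",
      primer_5p = "CCATGCGTAGCTGAACTCGGTC",
      l1_3p_end = "TGGCGCATCGATGGTCCTAGCGTTCGGACTCATGCCGGTC",
      l1_5p_end = "CAGTCGGCTAGACGTCATGGCCGATTCGCTAGGTCACGTC")
}

#' Default sample barcodes for the synthetic ATLAS-seq libraries
#'
#' Equal-length barcodes (so no barcode is a prefix of another), matched
#' exactly at the read 5' end during demultiplexing.
#'
#' @param n Number of barcodes to return (1-4).
#' @return Named character vector of 8-nt barcodes.
#' @export
atlasBarcodes <- function(n = 1) {
    bc <- c(S1 = "ACGTGCAT", S2 = "TGCAGTAC", S3 = "GATCCGTA", S4 = "CTAGTCGA")
    if (n < 1 || n > length(bc)) stop("n must be between 1 and ", length(bc))
    bc[seq_len(n)]
}

#' Synthetic full-length L1 consensus sequence
#'
#' A deterministic 6019-nt synthetic consensus emulating the anatomy a
#' subfamily-diagnostic analysis relies on: the first 40 nt equal the 5'-end
#' feature sequence (\code{l1_5p_end}), the last 40 nt equal the 3'-end
#' feature sequence (\code{l1_3p_end}), and the subfamily-diagnostic
#' trinucleotide ACA occupies 1-based positions 5927-5929 (the hallmark of
#' the youngest, transposition-active subfamily; older subfamilies carry ACG
#' or GAG at the same site).
#'
#' @param diagnostic Trinucleotide to place at positions 5927-5929
#'   (default \code{"ACA"}).
#' @return A single character string of length 6019.
#' @export
#' @examples
#' substr(syntheticL1Consensus(), 5927, 5929)
syntheticL1Consensus <- function(diagnostic = "ACA") {
    stopifnot(nchar(diagnostic) == 3L)
    ad <- atlasAdapters()
    mid <- with_seed(60190L, random_dna(6019L - 80L))
    cons <- paste0(ad[["l1_5p_end"]], mid, ad[["l1_3p_end"]])
    substr(cons, 5927L, 5929L) <- diagnostic
    cons
}

#' Lineage-specific 3' transduction tags
#'
#' Highly active ("hot") L1 elements fall into well-characterized lineages
#' whose members share a distinctive transduced sequence downstream of the
#' element, inherited from the lineage founder. Three such lineages are
#' traced here through short diagnostic tags searched in junction reads.
#'
#' @return Named character vector of tag sequences for the AC002980, RP and
#'   LRE3 lineages.
#' @export
lineageTags <- function() {
    c(AC002980 = "GCTTTATTGAGGTGTAACCAGCA",
      RP       = "TAAATTTAAAACTTTTTTTTTT",
      LRE3     = "CGGAATAGACATTTTGCTTTTCT")
}
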