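#' @importFrom methods new is validObject slot slotNames
#' @importFrom stats rbinom rgeom rpois runif hclust dist
#' @importFrom utils read.table write.table
NULL

# Evaluate `expr` with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has_seed) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

# Random DNA string of length n (uses the current RNG stream).
random_dna <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# substring helpers on parallel sequence/quality strings
cut_tail <- function(s, keep) substr(s, 1L, keep)
cut_head <- function(s, drop) substr(s, drop + 1L, nchar(s))
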