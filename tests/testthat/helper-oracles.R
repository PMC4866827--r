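# Independent brute-force oracles used by the property tests. These stay
# deliberately naive (quadratic scans, exhaustive enumeration) and never
# share code with the implementation they check.

# Exhaustive semi-global adapter search: returns the best (n_errors,
# matched_len) pair over all admissible occurrences, or NULL.
oracle_find_adapter <- function(seq, adapter, error_rate, min_overlap,
                                anchor) {
    n <- nchar(seq); m <- nchar(adapter)
    best <- NULL
    consider <- function(err, klen) {
        if (klen < min_overlap || err > floor(error_rate * klen)) return()
        if (is.null(best) || err < best$err ||
            (err == best$err && klen > best$klen))
            best <<- list(err = err, klen = klen)
    }
    ed <- function(a, b) utils::adist(a, b)[1, 1]
    for (s in seq_len(n)) for (e in s:n)
        consider(ed(substr(seq, s, e), adapter), m)
    if (anchor == "three_prime" && min_overlap <= m - 1)
        for (k in seq(max(1, min_overlap), m - 1))
            for (s in seq_len(n))
                consider(ed(substr(seq, s, n), substr(adapter, 1, k)), k)
    if (anchor == "five_prime" && min_overlap <= m - 1)
        for (k in seq(max(1, min_overlap), m - 1))
            for (e in seq_len(n))
                consider(ed(substr(seq, 1, e),
                            substr(adapter, m - k + 1, m)), k)
    best
}

# Brute-force 3' quality trim: cut point maximizing sum(threshold - q)
# over the removed suffix; no trim when no suffix has a positive sum.
oracle_quality_trim <- function(qual, threshold) {
    q <- utf8ToInt(qual) - 33L
    n <- length(q)
    if (n == 0) return(0L)
    sums <- vapply(seq_len(n), function(k) sum(threshold - q[k:n]),
                   numeric(1))
    if (max(sums) <= 0) return(n)  # keep everything
    max(which(sums == max(sums))) - 1L  # bases kept
}

# O(n^2) transitive-closure merge of same-strand intervals with gap <= gap.
oracle_cluster <- function(df, gap) {
    # df: chrom, start, end, strand (1-based closed)
    n <- nrow(df)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i >= j) next
        if (df$chrom[i] != df$chrom[j] || df$strand[i] != df$strand[j])
            next
        sep <- max(df$start[i], df$start[j]) -
            min(df$end[i], df$end[j]) - 1L
        if (sep <= gap) {
            ri <- find(i); rj <- find(j)
            parent[max(ri, rj)] <- min(ri, rj)
        }
    }
    comp <- vapply(seq_len(n), find, integer(1))
    out <- do.call(rbind, lapply(split(seq_len(n), comp), function(ii)
        data.frame(chrom = df$chrom[ii[1]], start = min(df$start[ii]),
                   end = max(df$end[ii]), strand = df$strand[ii[1]],
                   n = length(ii), stringsAsFactors = FALSE)))
    out <- out[order(out$chrom, out$start, out$strand), , drop = FALSE]
    rownames(out) <- NULL
    out
}

# Naive quadratic primer-site scan (positions, strands, longest form per
# priming position).
oracle_primer_map <- function(genome_str, primer, min_suffix,
                              full_mismatches) {
    G <- nchar(genome_str)
    m <- nchar(primer)
    rc <- function(x) as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(x)))
    mism <- function(a, b)
        sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    rows <- list()
    for (L in seq(min_suffix, m)) {
        pat <- substr(primer, m - L + 1L, m)
        budget <- if (L == m) full_mismatches else 0L
        patr <- rc(pat)
        for (i in seq_len(G - L + 1L)) {
            w <- substr(genome_str, i, i + L - 1L)
            if (mism(w, pat) <= budget)
                rows[[length(rows) + 1L]] <- data.frame(
                    start = i, end = i + L - 1L, strand = "+",
                    L = L, prime_pos = i + L - 1L)
            if (mism(w, patr) <= budget)
                rows[[length(rows) + 1L]] <- data.frame(
                    start = i, end = i + L - 1L, strand = "-",
                    L = L, prime_pos = i)
        }
    }
    if (length(rows) == 0)
        return(data.frame(start = integer(), end = integer(),
                          strand = character(), L = integer()))
    df <- do.call(rbind, rows)
    keep <- do.call(rbind, lapply(
        split(df, paste(df$strand, df$prime_pos)),
        function(g) g[which.max(g$L), , drop = FALSE]))
    keep <- keep[order(keep$start, keep$strand), , drop = FALSE]
    rownames(keep) <- NULL
    keep[, c("start", "end", "strand", "L")]
}

# Exhaustive minimum-cardinality subset reaching half the total.
oracle_half_total <- function(v) {
    n <- length(v)
    tot <- sum(v)
    best <- n
    for (mask in seq_len(2^n - 1)) {
        sel <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))
        if (sum(v[sel]) >= tot / 2) best <- min(best, sum(sel))
    }
    best
}
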