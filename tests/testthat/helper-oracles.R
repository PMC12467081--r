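# Independent oracles kept deliberately separate from the implementation
# paths they check.

# r2 by direct covariance arithmetic over pairwise-complete entries
r2Oracle <- function(x, y) {
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    n <- length(x)
    sxy <- sum(x * y) / n - mean(x) * mean(y)
    sxx <- sum(x * x) / n - mean(x)^2
    syy <- sum(y * y) / n - mean(y)^2
    if (sxx == 0 || syy == 0) return(0)
    (sxy * sxy) / (sxx * syy)
}

# interval merging by explicit union-find over pairwise gap checks
mergeOracle <- function(chrom, start, end, gapTol) {
    n <- length(start)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i >= j || chrom[i] != chrom[j]) next
        gap <- max(start[i], start[j]) - min(end[i], end[j]) - 1L
        if (gap <= gapTol) {
            ri <- find(i); rj <- find(j)
            if (ri != rj) parent[ri] <- rj
        }
    }
    roots <- vapply(seq_len(n), find, integer(1L))
    comp <- split(seq_len(n), roots)
    out <- do.call(rbind, lapply(comp, function(ix)
        data.frame(chrom = chrom[ix[1L]], start = min(start[ix]),
                   end = max(end[ix]), n = length(ix))))
    out[order(out$chrom, out$start), , drop = FALSE]
}

# global affine alignment score through an independent library
.oracleSub <- local({
    l <- c("A", "C", "G", "T", "N")
    m <- matrix(-3, 5, 5, dimnames = list(l, l))
    diag(m) <- 2
    m["N", ] <- -3; m[, "N"] <- -3
    m
})

alignScoreOracle <- function(a, b)
    Biostrings::score(Biostrings::pairwiseAlignment(
        a, b, type = "global", substitutionMatrix = .oracleSub,
        gapOpening = 5, gapExtension = 2))

# codon-table translation through seqinr, independent of Biostrings
translateOracle <- function(cds) {
    paste(seqinr::translate(strsplit(tolower(cds), "")[[1L]]),
          collapse = "")
}

randSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                    replace = TRUE), collapse = "")
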