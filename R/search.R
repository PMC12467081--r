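## Seed-and-extend homology search: exact k-mer seeds of the query are
## located in the member genome on both strands (2-bit k-mer hashing),
## seeds sharing a diagonal band are chained into candidate loci, and
## each candidate window is extended and scored by affine-gap local
## alignment. The highest-scoring hit passing the identity and coverage
## thresholds is the best hit.

#' Best-hit homology search in a member genome
#'
#' Exact \code{seedK}-mers of the query (non-overlapping, skipping any
#' containing non-ACGT characters) are located on both strands of every
#' member sequence; seeds on a common diagonal band are chained, and each
#' candidate locus is extended and scored by local alignment (match +2,
#' mismatch -3, gap open -5, gap extend -2; blastn-like defaults). The
#' highest-scoring hit passing \code{minIdentity} and \code{minCoverage}
#' is returned; score ties break to the lexicographically lower
#' (sequence name, start). Absence of an adequate hit is a value
#' (\code{NULL}), not an error.
#'
#' @param query a \code{DNAString}, character string, or the list
#'   returned by \code{\link{extractGeneSeq}}/\code{\link{extractMrna}}.
#' @param memberGenome named \code{DNAStringSet}.
#' @param seedK exact-seed length (default 15).
#' @param minIdentity minimum fraction of identical columns in the local
#'   alignment (default 0.8).
#' @param minCoverage minimum fraction of the query covered by the local
#'   alignment (default 0.5).
#' @param band diagonal tolerance in bp when chaining seeds
#'   (default 100).
#' @param maxCandidates candidate windows scored per strand and sequence
#'   (default 8; windows with the most seeds first).
#' @return one-row data.frame (chrom, strand, start, end on the forward
#'   strand, score, identity, coverage, n_seeds) or \code{NULL} when no
#'   hit passes the thresholds. Identity is the fraction of identical
#'   columns of the local alignment; coverage the fraction of the query
#'   it spans.
#' @export
bestHitSearch <- function(query, memberGenome, seedK = 15L,
                          minIdentity = 0.8, minCoverage = 0.5,
                          band = 100L, maxCandidates = 8L) {
    if (is.list(query)) query <- query$seq
    qchar <- toupper(as.character(query))
    qlen <- nchar(qchar)
    if (qlen < seedK) stop("query shorter than seedK")
    hits <- list()
    for (chrom in names(memberGenome)) {
        contig <- memberGenome[[chrom]]
        clen <- length(contig)
        for (strand in c("+", "-")) {
            subject <- if (strand == "+") contig else
                Biostrings::reverseComplement(contig)
            schar <- toupper(as.character(subject))
            sm <- .seedMatch(qchar, schar, as.integer(seedK),
                             as.integer(seedK))
            if (!nrow(sm)) next
            qpos <- sm[, "qpos"]; spos <- sm[, "spos"]
            diag <- spos - qpos
            o <- order(diag)
            diag <- diag[o]; qpos <- qpos[o]; spos <- spos[o]
            grp <- cumsum(c(1L, diff(diag) > band))
            sizes <- table(grp)
            top <- utils::head(names(sort(sizes, decreasing = TRUE)),
                               maxCandidates)
            for (g in top) {
                sel <- grp == as.integer(g)
                ws <- max(1L, min(spos[sel] - qpos[sel] + 1L) - band)
                we <- min(clen,
                          max(spos[sel] + (qlen - qpos[sel])) + band)
                sw <- .swLocal(qchar, substr(schar, ws, we),
                               2L, -3L, 5L, 2L)
                if (sw$score <= 0) next
                cols <- strsplit(sw$aligned1, "", fixed = TRUE)[[1L]]
                colm <- strsplit(sw$aligned2, "", fixed = TRUE)[[1L]]
                ident <- mean(cols == colm)
                cov <- (sw$end1 - sw$start1 + 1L) / qlen
                os <- ws + sw$start2 - 1L
                oe <- ws + sw$end2 - 1L
                if (strand == "+") {
                    fs <- os; fe <- oe
                } else {
                    fs <- clen - oe + 1L; fe <- clen - os + 1L
                }
                hits[[length(hits) + 1L]] <- data.frame(
                    chrom = chrom, strand = strand, start = fs, end = fe,
                    score = sw$score, identity = ident,
                    coverage = cov, n_seeds = sum(sel),
                    stringsAsFactors = FALSE)
            }
        }
    }
    if (!length(hits)) return(NULL)
    tab <- do.call(rbind, hits)
    tab <- tab[tab$identity >= minIdentity & tab$coverage >= minCoverage,
               , drop = FALSE]
    if (!nrow(tab)) return(NULL)
    tab <- tab[order(-tab$score, tab$chrom, tab$start), , drop = FALSE]
    rownames(tab) <- NULL
    tab[1L, ]
}

#' Extract a hit span with flanks, co-oriented with the query
#'
#' Member subsequence \code{[start - flank, end + flank]}, clipped at
#' contig bounds, reverse-complemented when the hit is on the minus
#' strand so it reads in the same orientation as the query.
#'
#' @param hit one-row data.frame from \code{\link{bestHitSearch}}.
#' @param memberGenome named \code{DNAStringSet}.
#' @param flank non-negative flank in bp.
#' @return a \code{DNAString}.
#' @export
extractHitWithFlanks <- function(hit, memberGenome, flank = 0L) {
    stopifnot(is.data.frame(hit), nrow(hit) == 1L, flank >= 0)
    contig <- memberGenome[[hit$chrom]]
    if (is.null(contig)) stop("hit names unknown sequence: ", hit$chrom)
    a <- max(1L, hit$start - as.integer(flank))
    b <- min(length(contig), hit$end + as.integer(flank))
    s <- Biostrings::subseq(contig, a, b)
    if (hit$strand == "-") s <- Biostrings::reverseComplement(s)
    s
}
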