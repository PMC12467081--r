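## Pairwise global alignment of a labeled reference sequence against a
## member sequence, with feature-label projection onto alignment columns.

#' Global alignment of a labeled reference against a member sequence
#'
#' Needleman-Wunsch global alignment with affine gap penalties (defaults:
#' match +2, mismatch -3, gap open -5, gap extend -2; a gap of length L
#' costs open + L x extend). The reference's per-position feature labels
#' are projected onto alignment columns; columns where the reference row
#' is a gap (an insertion in the member) inherit the label of the
#' preceding reference position, i.e. of the enclosing reference feature
#' interval.
#'
#' @param ref list from \code{\link{extractGeneSeq}} or
#'   \code{\link{extractMrna}} (sequence plus feature map), or a plain
#'   sequence, in which case \code{labels} must be supplied.
#' @param memberSeq \code{DNAString} or character (non-empty).
#' @param labels optional character vector of per-position labels when
#'   \code{ref} is a plain sequence.
#' @param match,mismatch,gapOpen,gapExtend scoring parameters (penalties
#'   positive).
#' @return list of class \code{pairAlignment}: \code{ref_aln} and
#'   \code{member_aln} (gapped strings), \code{col_label} (per column),
#'   \code{score}.
#' @export
alignPair <- function(ref, memberSeq, labels = NULL, match = 2,
                      mismatch = -3, gapOpen = 5, gapExtend = 2) {
    if (is.list(ref)) {
        labels <- ref$label
        refSeq <- as.character(ref$seq)
    } else {
        refSeq <- as.character(ref)
    }
    memberSeq <- as.character(memberSeq)
    if (!nchar(refSeq) || !nchar(memberSeq))
        stop("both sequences must be non-empty")
    if (is.null(labels)) labels <- rep("noncoding", nchar(refSeq))
    stopifnot(length(labels) == nchar(refSeq))
    nw <- .nwAffine(toupper(refSeq), toupper(memberSeq), match, mismatch,
                    gapOpen, gapExtend)
    ra <- strsplit(nw$aligned1, "", fixed = TRUE)[[1L]]
    refpos <- cumsum(ra != "-")
    col_label <- labels[pmax(refpos, 1L)]  # leading insertions take the
                                           # first reference label
    structure(list(ref_aln = nw$aligned1, member_aln = nw$aligned2,
                   col_label = col_label, score = nw$score),
              class = "pairAlignment")
}

#' @export
print.pairAlignment <- function(x, ...) {
    cat("pairAlignment:", nchar(x$ref_aln), "columns, score",
        x$score, "\n")
    invisible(x)
}

#' Write a pairwise alignment as FASTA
#'
#' Two gapped records (reference first) for visual assessment in any
#' alignment viewer.
#'
#' @param aln a \code{pairAlignment}.
#' @param path output path.
#' @param names record names (length 2).
#' @return \code{path}, invisibly.
#' @export
writeAlignmentFasta <- function(aln, path,
                                names = c("reference", "member")) {
    writeLines(c(paste0(">", names[1L]), aln$ref_aln,
                 paste0(">", names[2L]), aln$member_aln), path)
    invisible(path)
}
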