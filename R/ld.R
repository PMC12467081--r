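## Linkage-disequilibrium decay: pairwise r2 of genotype dosages, the
## binned genome-wide decay curve, and the linked-region half-width used
## to size candidate intervals.

#' Pairwise linkage disequilibrium (r-squared) of two dosage vectors
#'
#' Squared Pearson correlation of genotype dosages over pairwise-complete
#' accessions (the composite, Plink-style estimator). Returns 0 when either
#' vector is constant after pairwise deletion, so monomorphic markers do
#' not poison decay bins.
#'
#' @param d1,d2 numeric dosage vectors of equal length (0/1/2/NA).
#' @return r-squared in [0, 1].
#' @examples
#' d <- c(0, 1, 2, 0, 1)
#' pairwiseR2(d, 2 - d)  # perfect repulsion is still r2 = 1
#' @export
pairwiseR2 <- function(d1, d2) {
    stopifnot(length(d1) == length(d2))
    ok <- !is.na(d1) & !is.na(d2)
    if (sum(ok) < 2L)
        stop("insufficient data: fewer than 2 pairwise-complete accessions")
    x <- d1[ok]; y <- d2[ok]
    if (stats::var(x) == 0 || stats::var(y) == 0) return(0)
    unname(stats::cor(x, y)^2)
}

#' Genome-wide LD decay curve
#'
#' All intra-chromosome marker pairs separated by at most \code{maxDist}
#' contribute their dosage r-squared to the bin of their distance; the
#' per-bin mean is reported. Inter-chromosome pairs are excluded (distance
#' undefined); bins with no pairs are NA.
#'
#' @param ms a sorted \linkS4class{MarkerSet}.
#' @param maxDist maximum pair distance in bp (default 200000, covering
#'   the range over which decay levels out).
#' @param binWidth bin width in bp (default 1000).
#' @return a \linkS4class{DecayCurve}.
#' @export
decayCurve <- function(ms, maxDist = 200000, binWidth = 1000) {
    stopifnot(is(ms, "MarkerSet"), binWidth > 0, maxDist >= binWidth)
    nb <- ceiling(maxDist / binWidth)
    sums <- numeric(nb); counts <- integer(nb)
    rr <- SummarizedExperiment::rowRanges(ms)
    chrom <- as.character(GenomeInfoDb::seqnames(rr))
    pos <- BiocGenerics::start(rr)
    d <- dosages(ms)
    for (ch in unique(chrom)) {
        idx <- which(chrom == ch)
        if (length(idx) < 2L) next
        p <- pos[idx]
        ## r2 matrix over pairwise-complete accessions; constant markers
        ## give NA correlations which we map to 0 by design
        cc <- suppressWarnings(
            stats::cor(t(d[idx, , drop = FALSE]),
                       use = "pairwise.complete.obs"))
        cc[is.na(cc)] <- 0
        r2 <- cc^2
        pr <- which(upper.tri(r2), arr.ind = TRUE)
        dist <- abs(p[pr[, 2L]] - p[pr[, 1L]])
        keep <- dist <= maxDist & dist > 0L
        if (!any(keep)) next
        b <- pmin(nb, floor(dist[keep] / binWidth) + 1L)
        v <- r2[pr[keep, , drop = FALSE]]
        for (k in unique(b)) {
            sel <- b == k
            sums[k] <- sums[k] + sum(v[sel])
            counts[k] <- counts[k] + sum(sel)
        }
    }
    mean_r2 <- ifelse(counts > 0L, sums / pmax(counts, 1L), NA_real_)
    new("DecayCurve",
        binStart = (seq_len(nb) - 1) * binWidth,
        binEnd = pmin(seq_len(nb) * binWidth, maxDist),
        meanR2 = mean_r2, pairCount = counts, maxDist = maxDist)
}

#' Linked-region half-width from a decay curve
#'
#' The distance out to which a marker is taken to tag its neighbourhood:
#' the left edge of the first non-empty bin whose mean r-squared falls
#' below \code{threshold}. If the curve never crosses the threshold the
#' curve's maximum distance is returned with attribute
#' \code{crossed = FALSE}.
#'
#' @param curve a \linkS4class{DecayCurve}.
#' @param threshold r-squared threshold in (0, 1); 0.1 is the conventional
#'   cut for delimiting a linked region.
#' @return half-width in bp, with logical attribute \code{crossed}.
#' @export
linkedRegionHalfwidth <- function(curve, threshold = 0.1) {
    stopifnot(is(curve, "DecayCurve"), threshold > 0, threshold < 1)
    ok <- curve@pairCount > 0L
    if (!any(ok)) stop("empty decay curve: no bins with pairs")
    hit <- which(ok & curve@meanR2 < threshold)
    if (length(hit)) {
        out <- curve@binStart[hit[1L]]
        attr(out, "crossed") <- TRUE
    } else {
        out <- curve@maxDist
        attr(out, "crossed") <- FALSE
    }
    out
}
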