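## Marker filtering and per-marker allele statistics.

#' Keep only biallelic sites
#'
#' Retains markers with exactly one reference and one alternate allele,
#' preserving relative order. Idempotent; commutes with
#' \code{\link{filterMissingness}}.
#'
#' @param ms a \linkS4class{MarkerSet}.
#' @return the filtered \linkS4class{MarkerSet} (possibly empty).
#' @export
filterBiallelic <- function(ms) {
    stopifnot(is(ms, "MarkerSet"))
    keep <- SummarizedExperiment::rowData(ms)$n_alt == 1L
    ms[keep, ]
}

#' Remove markers with too much missing data
#'
#' A marker is retained when its missing fraction is strictly below
#' \code{maxMissing}: sites where \code{maxMissing} (default 20\%) or more
#' of the accessions are missing are removed.
#'
#' @param ms a \linkS4class{MarkerSet}.
#' @param maxMissing removal threshold in [0, 1]; default 0.2.
#' @return the filtered \linkS4class{MarkerSet}.
#' @examples
#' d <- matrix(c(NA, NA, rep(0L, 8),  NA, rep(1L, 9)), nrow = 2,
#'             byrow = TRUE)
#' ms <- MarkerSet(d, rep("chr1", 2), c(10L, 20L), c("A", "C"),
#'                 c("G", "T"))
#' nrow(filterMissingness(ms, 0.2))  # the 2/10-missing marker is removed
#' @export
filterMissingness <- function(ms, maxMissing = 0.2) {
    stopifnot(is(ms, "MarkerSet"), maxMissing >= 0, maxMissing <= 1)
    d <- dosages(ms)
    frac <- rowMeans(is.na(d))
    ms[frac < maxMissing, ]
}

#' Minor allele frequency
#'
#' For each marker, \code{min(p, 1 - p)} where \code{p} is the alternate
#' allele frequency \code{sum(dosage) / (2 * n_non_missing)} over
#' non-missing accessions. Values lie in [0, 0.5] and are invariant under
#' swapping ref/alt (dosage d -> 2 - d).
#'
#' @param ms a \linkS4class{MarkerSet}, or a single dosage vector.
#' @return named numeric vector of MAFs (or a single value for a vector
#'   input). A marker with no non-missing dosage is an error.
#' @examples
#' minorAlleleFrequency(c(1, 1, rep(0, 8)))  # 2 alt alleles / 20 -> 0.1
#' @export
minorAlleleFrequency <- function(ms) {
    d <- if (is(ms, "MarkerSet")) dosages(ms) else
        matrix(ms, nrow = 1L)
    n <- rowSums(!is.na(d))
    if (any(n == 0L))
        stop("undefined allele frequency: marker(s) with all dosages ",
             "missing: ",
             paste(utils::head(rownames(d)[n == 0L]), collapse = ", "))
    p <- rowSums(d, na.rm = TRUE) / (2 * n)
    maf <- pmin(p, 1 - p)
    if (is(ms, "MarkerSet")) stats::setNames(maf, rownames(d)) else
        unname(maf)
}
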