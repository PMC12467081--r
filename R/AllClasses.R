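#' @import methods
#' @importFrom Rcpp sourceCpp
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importClassesFrom GenomicRanges GRanges GRangesList
#' @useDynLib panQTL, .registration = TRUE
NULL

#' MarkerSet: biallelic (and flagged multi-allelic) variant sites with
#' per-accession genotype dosages
#'
#' A \code{MarkerSet} extends
#' \linkS4class{RangedSummarizedExperiment}: one row per variant site, one
#' column per accession, and a single \code{"dosage"} assay holding the count
#' of non-reference alleles (0, 1, 2, or \code{NA} for missing). Row ranges
#' are 1-based single-base positions in VCF convention (the POS of the
#' left-anchored record); row metadata carry \code{ref}, \code{alt}
#' (comma-separated when multi-allelic), \code{n_alt}, and
#' \code{marker_type} (\code{"snp"} iff both alleles have length 1,
#' otherwise \code{"indel"}; \code{"multi"} for multi-allelic records, which
#' are retained on reading but flagged for removal by
#' \code{\link{filterBiallelic}}).
#'
#' Rows are always sorted by (chromosome, position); every filter preserves
#' that order.
#'
#' @seealso \code{\link{readMarkerVcf}}, \code{\link{filterBiallelic}},
#'   \code{\link{filterMissingness}}, \code{\link{minorAlleleFrequency}}
#' @aliases MarkerSet
#' @exportClass MarkerSet
setClass("MarkerSet", contains = "RangedSummarizedExperiment")

.validMarkerSet <- function(object) {
    msg <- NULL
    if (!"dosage" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'dosage' is required")
    else {
        d <- SummarizedExperiment::assay(object, "dosage")
        bad <- !(d %in% c(0L, 1L, 2L) | is.na(d))
        if (any(bad))
            msg <- c(msg, "dosages must be 0, 1, 2 or NA")
    }
    rd <- SummarizedExperiment::rowData(object)
    need <- c("ref", "alt", "n_alt", "marker_type")
    miss <- setdiff(need, colnames(rd))
    if (length(miss))
        msg <- c(msg, paste0("rowData lacks column(s): ",
                             paste(miss, collapse = ", ")))
    if (nrow(object) > 1L) {
        rr <- SummarizedExperiment::rowRanges(object)
        o <- order(as.character(GenomeInfoDb::seqnames(rr)),
                   BiocGenerics::start(rr))
        if (!identical(o, seq_len(nrow(object))))
            msg <- c(msg, "markers must be sorted by (chrom, pos)")
    }
    if (is.null(msg)) TRUE else msg
}
setValidity("MarkerSet", .validMarkerSet)

#' Construct a MarkerSet from a dosage matrix
#'
#' @param dosage integer matrix, markers x accessions; values 0/1/2/NA.
#' @param chrom character vector of chromosome names, one per marker.
#' @param pos integer vector of 1-based positions.
#' @param ref,alt character vectors of reference and alternate alleles;
#'   \code{alt} may contain comma-separated alleles for multi-allelic sites.
#' @param id optional marker identifiers (default \code{chrom_pos}).
#' @param accessions optional accession identifiers (default from
#'   \code{colnames(dosage)}).
#' @return A \linkS4class{MarkerSet}, sorted by (chrom, pos).
#' @examples
#' ms <- MarkerSet(matrix(c(0, 1, 2, NA), 2, 2,
#'                        dimnames = list(NULL, c("a1", "a2"))),
#'                 chrom = c("chr1", "chr1"), pos = c(100L, 250L),
#'                 ref = c("A", "T"), alt = c("G", "TTA"))
#' markerType(ms)
#' @export
MarkerSet <- function(dosage, chrom, pos, ref, alt, id = NULL,
                      accessions = colnames(dosage)) {
    dosage <- as.matrix(dosage)
    stopifnot(length(chrom) == nrow(dosage), length(pos) == nrow(dosage),
              length(ref) == nrow(dosage), length(alt) == nrow(dosage))
    if (any(pos < 1L)) stop("positions must be >= 1")
    if (any(ref == alt)) stop("ref and alt alleles must differ")
    if (is.null(accessions))
        accessions <- paste0("acc", seq_len(ncol(dosage)))
    if (is.null(id)) id <- paste(chrom, pos, sep = "_")
    n_alt <- lengths(strsplit(alt, ",", fixed = TRUE))
    mtype <- ifelse(n_alt > 1L, "multi",
                    ifelse(nchar(ref) == 1L & nchar(alt) == 1L,
                           "snp", "indel"))
    rr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L))
    names(rr) <- id
    S4Vectors::mcols(rr) <- S4Vectors::DataFrame(
        ref = as.character(ref), alt = as.character(alt),
        n_alt = as.integer(n_alt), marker_type = mtype)
    storage.mode(dosage) <- "integer"
    dimnames(dosage) <- list(id, accessions)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(dosage = dosage), rowRanges = rr)
    o <- order(as.character(GenomeInfoDb::seqnames(rr)),
               BiocGenerics::start(rr))
    new("MarkerSet", se[o, ])
}

setMethod("show", "MarkerSet", function(object) {
    cat("MarkerSet with", nrow(object), "markers x", ncol(object),
        "accessions\n")
    tt <- table(SummarizedExperiment::rowData(object)$marker_type)
    cat("  types:", paste(names(tt), tt, sep = "=", collapse = ", "), "\n")
    d <- SummarizedExperiment::assay(object, "dosage")
    cat(sprintf("  missing dosage fraction: %.3f\n", mean(is.na(d))))
    invisible(NULL)
})

#' GenomeAnnotation: strand-aware gene models
#'
#' Holds gene-level spans plus per-gene exon, CDS, and UTR segments as
#' \linkS4class{GRangesList}s keyed by gene id. CDS segments carry a
#' \code{phase} metadata column. Supports spliced mRNA extraction and
#' codon-aware alignment classification.
#'
#' @aliases GenomeAnnotation
#' @exportClass GenomeAnnotation
setClass("GenomeAnnotation",
         representation(genes = "GRanges", exons = "GRangesList",
                        cds = "GRangesList", utrs = "GRangesList"))

.validGenomeAnnotation <- function(object) {
    msg <- NULL
    ids <- names(object@genes)
    if (is.null(ids) || anyDuplicated(ids))
        msg <- c(msg, "gene spans must carry unique gene-id names")
    for (slot in c("exons", "cds", "utrs")) {
        g <- methods::slot(object, slot)
        if (!all(names(g) %in% ids))
            msg <- c(msg, paste0(slot, " keyed by unknown gene ids"))
    }
    if (!all(names(object@cds) %in% names(object@exons)))
        msg <- c(msg, "every CDS-bearing gene needs exons")
    if (is.null(msg)) TRUE else msg
}
setValidity("GenomeAnnotation", .validGenomeAnnotation)

#' @param genes GRanges of gene spans, named by gene id, with strand.
#' @param exons,cds,utrs GRangesList keyed by gene id; \code{cds} elements
#'   should carry an integer \code{phase} metadata column (0 assumed when
#'   absent).
#' @return A \code{GenomeAnnotation}.
#' @rdname GenomeAnnotation-class
#' @export
GenomeAnnotation <- function(genes, exons, cds, utrs =
                                 GenomicRanges::GRangesList()) {
    sortl <- function(grl) {
        GenomicRanges::GRangesList(lapply(grl, function(g)
            g[order(BiocGenerics::start(g))]))
    }
    new("GenomeAnnotation", genes = genes, exons = sortl(exons),
        cds = sortl(cds), utrs = sortl(utrs))
}

setMethod("show", "GenomeAnnotation", function(object) {
    cat("GenomeAnnotation:", length(object@genes), "genes on",
        length(unique(as.character(
            GenomeInfoDb::seqnames(object@genes)))), "sequence(s)\n")
    invisible(NULL)
})

#' DecayCurve: binned linkage-disequilibrium decay
#'
#' Mean pairwise r-squared of genotype dosages per physical-distance bin.
#' Bins with no contributing pairs have \code{NA} mean (undefined, not
#' zero).
#'
#' @aliases DecayCurve
#' @exportClass DecayCurve
setClass("DecayCurve",
         representation(binStart = "numeric", binEnd = "numeric",
                        meanR2 = "numeric", pairCount = "integer",
                        maxDist = "numeric"))

.validDecayCurve <- function(object) {
    msg <- NULL
    n <- length(object@binStart)
    if (length(object@binEnd) != n || length(object@meanR2) != n ||
        length(object@pairCount) != n)
        msg <- c(msg, "bin vectors must have equal length")
    if (n > 0 && (any(object@binEnd < object@binStart) ||
                  is.unsorted(object@binStart, strictly = TRUE)))
        msg <- c(msg, "bins must be increasing and non-overlapping")
    ok <- object@pairCount > 0L
    if (any(!is.na(object@meanR2[!ok])))
        msg <- c(msg, "empty bins must have NA mean r2")
    if (any(object@meanR2[ok] < -1e-12 | object@meanR2[ok] > 1 + 1e-12,
            na.rm = TRUE))
        msg <- c(msg, "mean r2 out of [0,1]")
    if (is.null(msg)) TRUE else msg
}
setValidity("DecayCurve", .validDecayCurve)

setMethod("show", "DecayCurve", function(object) {
    cat("DecayCurve:", length(object@binStart), "bins to",
        object@maxDist, "bp;",
        sum(object@pairCount), "marker pairs\n")
    invisible(NULL)
})

#' @describeIn DecayCurve-class coerce to a data.frame with columns
#'   bin_start, bin_end, mean_r2, n_pairs.
#' @param x a DecayCurve
#' @param ... unused
#' @export
setMethod("as.data.frame", "DecayCurve", function(x, ...) {
    data.frame(bin_start = x@binStart, bin_end = x@binEnd,
               mean_r2 = x@meanR2, n_pairs = x@pairCount)
})

.PAIRWISE_CLASSES <- c("PROTEIN_DIFF", "SILENT_CDS", "NONCODING_ONLY",
                       "NO_DIFF", "NO_MATCH")
.GENE_CATEGORIES <- c("PROTEIN_DIFF_4PLUS", "PROTEIN_DIFF_1TO3",
                      "SILENT_CDS", "NONCODING_ONLY", "NO_MATCH_OR_NO_DIFF")

#' Pairwise classification and gene category levels
#'
#' \code{pairwiseClasses()} returns the five per-member alignment verdicts;
#' \code{geneCategories()} the five mutually exclusive, collectively
#' exhaustive per-gene categories (protein differences in four or more
#' members; in one to three; silent CDS differences; non-coding differences
#' only; no match or no differences).
#' @return character vector of level names.
#' @export
pairwiseClasses <- function() .PAIRWISE_CLASSES

#' @rdname pairwiseClasses
#' @export
geneCategories <- function() .GENE_CATEGORIES
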