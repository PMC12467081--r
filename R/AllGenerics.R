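#' Accessors for MarkerSet
#'
#' \code{dosages()} returns the integer dosage matrix (markers x
#' accessions), \code{accessionIds()} the accession names,
#' \code{markerIds()} the marker names, \code{markerType()} the per-marker
#' type (\code{snp}/\code{indel}/\code{multi}), \code{refAllele()} and
#' \code{altAllele()} the allele strings.
#'
#' @param x a \linkS4class{MarkerSet}
#' @return see description; vectors are in row (marker) order.
#' @name MarkerSet-accessors
NULL

#' @rdname MarkerSet-accessors
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))
#' @rdname MarkerSet-accessors
#' @export
setMethod("dosages", "MarkerSet", function(x)
    SummarizedExperiment::assay(x, "dosage"))

#' @rdname MarkerSet-accessors
#' @export
setGeneric("accessionIds", function(x) standardGeneric("accessionIds"))
#' @rdname MarkerSet-accessors
#' @export
setMethod("accessionIds", "MarkerSet", function(x) colnames(x))

#' @rdname MarkerSet-accessors
#' @export
setGeneric("markerIds", function(x) standardGeneric("markerIds"))
#' @rdname MarkerSet-accessors
#' @export
setMethod("markerIds", "MarkerSet", function(x) rownames(x))

#' @rdname MarkerSet-accessors
#' @export
setGeneric("markerType", function(x) standardGeneric("markerType"))
#' @rdname MarkerSet-accessors
#' @export
setMethod("markerType", "MarkerSet", function(x)
    stats::setNames(SummarizedExperiment::rowData(x)$marker_type,
                    rownames(x)))

#' @rdname MarkerSet-accessors
#' @export
setGeneric("refAllele", function(x) standardGeneric("refAllele"))
#' @rdname MarkerSet-accessors
#' @export
setMethod("refAllele", "MarkerSet", function(x)
    stats::setNames(SummarizedExperiment::rowData(x)$ref, rownames(x)))

#' @rdname MarkerSet-accessors
#' @export
setGeneric("altAllele", function(x) standardGeneric("altAllele"))
#' @rdname MarkerSet-accessors
#' @export
setMethod("altAllele", "MarkerSet", function(x)
    stats::setNames(SummarizedExperiment::rowData(x)$alt, rownames(x)))

#' Accessors for GenomeAnnotation
#'
#' @param x a \linkS4class{GenomeAnnotation}
#' @return \code{genes()} a named GRanges of gene spans; \code{exonsBy()},
#'   \code{cdsBy()}, \code{utrsBy()} GRangesLists keyed by gene id;
#'   \code{geneIds()} the gene id vector.
#' @name GenomeAnnotation-accessors
NULL

#' @rdname GenomeAnnotation-accessors
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))
#' @rdname GenomeAnnotation-accessors
#' @export
setMethod("genes", "GenomeAnnotation", function(x) x@genes)

#' @rdname GenomeAnnotation-accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname GenomeAnnotation-accessors
#' @export
setMethod("geneIds", "GenomeAnnotation", function(x) names(x@genes))

#' @rdname GenomeAnnotation-accessors
#' @export
setGeneric("exonsBy", function(x) standardGeneric("exonsBy"))
#' @rdname GenomeAnnotation-accessors
#' @export
setMethod("exonsBy", "GenomeAnnotation", function(x) x@exons)

#' @rdname GenomeAnnotation-accessors
#' @export
setGeneric("cdsBy", function(x) standardGeneric("cdsBy"))
#' @rdname GenomeAnnotation-accessors
#' @export
setMethod("cdsBy", "GenomeAnnotation", function(x) x@cds)

#' @rdname GenomeAnnotation-accessors
#' @export
setGeneric("utrsBy", function(x) standardGeneric("utrsBy"))
#' @rdname GenomeAnnotation-accessors
#' @export
setMethod("utrsBy", "GenomeAnnotation", function(x) x@utrs)
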