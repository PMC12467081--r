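## Flanked marker intervals, region merging, gene attachment, and
## gene-density arithmetic.

#' Build flanked intervals around markers
#'
#' One interval \code{[max(1, pos - flank), pos + flank]} per marker
#' (1-based inclusive), clipped at the chromosome start. The default
#' one-sided flank of 50 kb gives 100 kb spans, the mid-range linked-area
#' size suggested by genome-wide LD decay.
#'
#' @param markers a data.frame with columns \code{id}, \code{chrom},
#'   \code{pos} (see \code{\link{readMarkerTable}}), or a
#'   \linkS4class{MarkerSet}.
#' @param flank one-sided flank in bp (default 50000).
#' @return \code{GRanges} with an \code{marker_id} metadata column.
#' @export
buildIntervals <- function(markers, flank = 50000) {
    stopifnot(flank > 0)
    if (is(markers, "MarkerSet")) {
        rr <- SummarizedExperiment::rowRanges(markers)
        markers <- data.frame(id = names(rr),
                              chrom = as.character(
                                  GenomeInfoDb::seqnames(rr)),
                              pos = BiocGenerics::start(rr))
    }
    gr <- GenomicRanges::GRanges(
        markers$chrom,
        IRanges::IRanges(pmax(1L, markers$pos - flank),
                         markers$pos + flank))
    S4Vectors::mcols(gr)$marker_id <- as.character(markers$id)
    gr
}

#' Merge flanked intervals into distinct regions
#'
#' Intervals on the same chromosome whose gap
#' (\code{next_start - prev_end - 1}) is at most \code{gapTol} are merged
#' transitively; member marker ids are concatenated. Output regions are
#' sorted and pairwise disjoint per chromosome. The small default
#' tolerance absorbs near-touching intervals whose markers are in
#' practice linked.
#'
#' @param intervals \code{GRanges} from \code{\link{buildIntervals}} (a
#'   \code{marker_id} metadata column is used when present).
#' @param gapTol maximum merged gap in bp (default 1000).
#' @return \code{GRanges} of merged regions with \code{member_marker_ids}
#'   (CharacterList) and \code{n_markers} metadata columns.
#' @export
mergeIntervals <- function(intervals, gapTol = 1000) {
    stopifnot(is(intervals, "GRanges"), gapTol >= 0)
    if (!length(intervals))
        return(GenomicRanges::GRanges(
            member_marker_ids = IRanges::CharacterList(),
            n_markers = integer()))
    intervals <- GenomeInfoDb::sortSeqlevels(intervals)
    red <- GenomicRanges::reduce(BiocGenerics::sort(intervals),
                                 min.gapwidth = gapTol + 1L,
                                 with.revmap = TRUE)
    ids <- S4Vectors::mcols(intervals)$marker_id
    if (is.null(ids)) ids <- as.character(seq_along(intervals))
    srt <- BiocGenerics::sort(intervals)
    sids <- S4Vectors::mcols(srt)$marker_id
    if (is.null(sids)) sids <- as.character(seq_along(srt))
    members <- IRanges::CharacterList(
        lapply(S4Vectors::mcols(red)$revmap, function(i) sids[i]))
    S4Vectors::mcols(red) <- NULL
    S4Vectors::mcols(red)$member_marker_ids <- members
    S4Vectors::mcols(red)$n_markers <- lengths(members)
    red
}

#' Genes overlapping a region
#'
#' Gene ids whose gene-level span overlaps the region by at least 1 bp.
#' Each gene is reported once per merged region even when it spans several
#' member-marker intervals, preventing repeated analysis of the same gene
#' in composite regions.
#'
#' @param region \code{GRanges} (one or more regions).
#' @param annotation a \linkS4class{GenomeAnnotation}.
#' @return for a single region, a character vector of gene ids; for
#'   several, a \code{CharacterList} parallel to \code{region}.
#' @export
genesInRegion <- function(region, annotation) {
    stopifnot(is(region, "GRanges"), is(annotation, "GenomeAnnotation"))
    g <- genes(annotation)
    known <- as.character(GenomeInfoDb::seqnames(g))
    qchr <- as.character(GenomeInfoDb::seqnames(region))
    if (!all(qchr %in% known))
        stop("unknown chromosome(s): ",
             paste(setdiff(qchr, known), collapse = ", "))
    hits <- GenomicRanges::findOverlaps(region, g, ignore.strand = TRUE)
    res <- split(names(g)[S4Vectors::subjectHits(hits)],
                 factor(S4Vectors::queryHits(hits),
                        levels = seq_along(region)))
    res <- lapply(res, unique)
    if (length(region) == 1L) res[[1L]] else IRanges::CharacterList(res)
}

#' Expected gene count of a region from genome-wide density
#'
#' \code{region_len / (genome_size / n_genes)}: at roughly one gene per
#' 4.7 kb (a 650 Mbp assembly with 138 k gene models), a 100 kb region is
#' expected to hold 21 genes.
#'
#' @param regionLen region length in bp.
#' @param genomeSize assembled genome size in bp.
#' @param nGenes number of annotated gene models.
#' @return expected gene count (float).
#' @examples
#' expectedGeneCount(1e5, 650e6, 138000)
#' @export
expectedGeneCount <- function(regionLen, genomeSize, nGenes) {
    stopifnot(regionLen >= 0, genomeSize > 0)
    if (nGenes <= 0) stop("division error: nGenes must be positive")
    regionLen / (genomeSize / nGenes)
}

#' Write regions as BED
#'
#' Converts 1-based inclusive regions to BED's 0-based half-open
#' convention; the name column is the semicolon-joined member marker ids.
#'
#' @param regions \code{GRanges} from \code{\link{mergeIntervals}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeRegionsBed <- function(regions, path) {
    nm <- S4Vectors::mcols(regions)$member_marker_ids
    name <- if (is.null(nm)) "." else
        vapply(nm, paste, character(1L), collapse = ";")
    df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(regions)),
                     start = BiocGenerics::start(regions) - 1L,
                     end = BiocGenerics::end(regions),
                     name = name, score = 0L,
                     strand = ".")
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}
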