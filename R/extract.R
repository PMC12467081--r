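## Sequence extraction with per-position feature labels. Two modes:
## spliced mRNA (exons concatenated in transcript orientation) and
## genomic (unspliced gene body, introns labeled directly). Both return
## the sequence together with a column-to-feature map consumed by the
## alignment classifier.

.geneParts <- function(annotation, geneId) {
    g <- genes(annotation)
    if (!geneId %in% names(g)) stop("unknown gene id: ", geneId)
    gr <- g[geneId]
    list(gr = gr,
         chrom = as.character(GenomeInfoDb::seqnames(gr)),
         strand = {
             s <- as.character(BiocGenerics::strand(gr))
             if (s == "*") "+" else s
         },
         exons = exonsBy(annotation)[[geneId]],
         cds = cdsBy(annotation)[[geneId]],
         utrs = utrsBy(annotation)[[geneId]])
}

.checkBounds <- function(chrom, genome, from, to) {
    if (!chrom %in% names(genome))
        stop("coordinate error: unknown sequence '", chrom, "'")
    if (from < 1L || to > length(genome[[chrom]]))
        stop("coordinate error: feature [", from, ", ", to,
             "] outside '", chrom, "' (length ",
             length(genome[[chrom]]), ")")
    invisible(TRUE)
}

## Forward-strand per-position labels over window [wstart, wend]:
## flank < intron < utr (exonic non-CDS) < cds, later overriding earlier.
.windowLabels <- function(parts, wstart, wend) {
    n <- wend - wstart + 1L
    lab <- rep("flank", n)
    mark <- function(segs, value) {
        if (is.null(segs) || !length(segs)) return()
        for (i in seq_along(segs)) {
            a <- max(BiocGenerics::start(segs)[i], wstart) - wstart + 1L
            b <- min(BiocGenerics::end(segs)[i], wend) - wstart + 1L
            if (a <= b) lab[a:b] <<- value
        }
    }
    mark(parts$gr, "intron")
    mark(parts$exons, "utr")
    mark(parts$cds, "cds")
    lab
}

.orient <- function(seq, lab, strand) {
    if (strand == "-") {
        seq <- Biostrings::reverseComplement(seq)
        lab <- rev(lab)
    }
    list(seq = seq, lab = lab)
}

#' Extract an unspliced gene sequence with feature labels
#'
#' Returns the genomic gene span plus \code{flank} bases each side
#' (clipped at sequence bounds), oriented 5' to 3' in transcript
#' direction (reverse-complemented for minus-strand genes), with one
#' feature label per position: \code{cds}, \code{utr} (exonic
#' non-coding), \code{intron}, or \code{flank}. \code{cds_index} numbers
#' the CDS positions in translation order.
#'
#' @param annotation a \linkS4class{GenomeAnnotation}.
#' @param geneId gene identifier.
#' @param genome named \code{DNAStringSet} of reference sequences.
#' @param flank non-negative flank in bp (labeled non-coding).
#' @return list with elements \code{seq} (DNAString), \code{label}
#'   (character per position), \code{cds_index} (integer per position, NA
#'   off-CDS), \code{gene_id}, \code{chrom}, \code{strand},
#'   \code{window} (forward-strand start/end).
#' @export
extractGeneSeq <- function(annotation, geneId, genome, flank = 0L) {
    stopifnot(flank >= 0)
    p <- .geneParts(annotation, geneId)
    gs <- BiocGenerics::start(p$gr); ge <- BiocGenerics::end(p$gr)
    .checkBounds(p$chrom, genome, gs, ge)
    wstart <- max(1L, gs - as.integer(flank))
    wend <- min(length(genome[[p$chrom]]), ge + as.integer(flank))
    seq <- Biostrings::subseq(genome[[p$chrom]], wstart, wend)
    lab <- .windowLabels(p, wstart, wend)
    o <- .orient(seq, lab, p$strand)
    cds_index <- rep(NA_integer_, length(o$lab))
    is_cds <- o$lab == "cds"
    cds_index[is_cds] <- seq_len(sum(is_cds))
    .warnAmbiguous(o$seq, geneId)
    list(seq = o$seq, label = o$lab, cds_index = cds_index,
         gene_id = geneId, chrom = p$chrom, strand = p$strand,
         window = c(start = wstart, end = wend))
}

#' Extract a spliced mRNA with feature labels
#'
#' Exon sequences concatenated 5' to 3' in transcript orientation
#' (reverse-complemented for minus-strand genes). Each mRNA position is
#' labeled \code{cds} (with its index in the spliced coding sequence) or
#' \code{utr}; optional genomic flanking bases are included at both ends
#' and labeled \code{flank} (non-coding).
#'
#' @inheritParams extractGeneSeq
#' @return list as for \code{\link{extractGeneSeq}} (no \code{intron}
#'   labels: introns are spliced out).
#' @examples
#' fx <- makeReference(nChrom = 1, chromLen = 20000, nGenes = 3,
#'                     seed = 1)
#' m <- extractMrna(fx$annotation, geneIds(fx$annotation)[1], fx$genome)
#' substr(as.character(m$seq), which(m$label == "cds")[1],
#'        which(m$label == "cds")[1] + 2)  # "ATG"
#' @export
extractMrna <- function(annotation, geneId, genome, flank = 0L) {
    stopifnot(flank >= 0)
    p <- .geneParts(annotation, geneId)
    if (is.null(p$exons) || !length(p$exons))
        stop("gene ", geneId, " has no exons")
    gs <- BiocGenerics::start(p$gr); ge <- BiocGenerics::end(p$gr)
    .checkBounds(p$chrom, genome, gs, ge)
    ex <- p$exons[order(BiocGenerics::start(p$exons))]
    chunks <- character(0L); labs <- character(0L)
    for (i in seq_along(ex)) {
        a <- BiocGenerics::start(ex)[i]; b <- BiocGenerics::end(ex)[i]
        chunks <- c(chunks, as.character(
            Biostrings::subseq(genome[[p$chrom]], a, b)))
        l <- .windowLabels(p, a, b)
        labs <- c(labs, l)
    }
    seq <- Biostrings::DNAString(paste(chunks, collapse = ""))
    o <- .orient(seq, labs, p$strand)
    seqc <- as.character(o$seq); lab <- o$lab
    if (flank > 0L) {
        chromlen <- length(genome[[p$chrom]])
        left <- Biostrings::subseq(genome[[p$chrom]],
                                   max(1L, gs - as.integer(flank)),
                                   gs - 1L)
        right <- Biostrings::subseq(genome[[p$chrom]], ge + 1L,
                                    min(chromlen, ge + as.integer(flank)))
        if (p$strand == "-") {
            up <- as.character(Biostrings::reverseComplement(right))
            down <- as.character(Biostrings::reverseComplement(left))
        } else {
            up <- as.character(left); down <- as.character(right)
        }
        seqc <- paste0(up, seqc, down)
        lab <- c(rep("flank", nchar(up)), lab,
                 rep("flank", nchar(down)))
    }
    cds_index <- rep(NA_integer_, length(lab))
    is_cds <- lab == "cds"
    cds_index[is_cds] <- seq_len(sum(is_cds))
    out_seq <- Biostrings::DNAString(seqc)
    .warnAmbiguous(out_seq, geneId)
    list(seq = out_seq, label = lab, cds_index = cds_index,
         gene_id = geneId, chrom = p$chrom, strand = p$strand,
         window = c(start = gs, end = ge))
}

.warnAmbiguous <- function(seq, geneId) {
    freq <- Biostrings::alphabetFrequency(seq)
    acgt <- sum(freq[c("A", "C", "G", "T")])
    if (acgt < 0.5 * sum(freq))
        warning("gene ", geneId, ": more than 50% ambiguous (non-ACGT) ",
                "bases in extracted sequence")
    invisible(NULL)
}
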