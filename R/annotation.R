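## GFF3-backed gene models. Reading goes through rtracklayer; the writer
## emits the gene/mRNA/exon/CDS/UTR rows the reader consumes.

#' Read a GenomeAnnotation from GFF3
#'
#' Expects gene, mRNA, exon, CDS and (optionally) five_prime_UTR /
#' three_prime_UTR features linked by ID/Parent attributes. When a gene
#' has several mRNAs only the longest (primary) transcript is kept.
#'
#' @param path GFF3 file path.
#' @return a \linkS4class{GenomeAnnotation}.
#' @export
readAnnotation <- function(path) {
    gff <- rtracklayer::import(path, format = "gff3")
    ty <- as.character(gff$type)
    gene_gr <- gff[ty == "gene"]
    names(gene_gr) <- gene_gr$ID
    mrna <- gff[ty == "mRNA"]
    if (!length(gene_gr) && length(mrna)) {
        ## annotation without explicit gene rows: promote mRNAs
        gene_gr <- mrna
        names(gene_gr) <- gene_gr$ID
    }
    parent1 <- function(x) vapply(x$Parent, function(p)
        if (length(p)) as.character(p[1L]) else NA_character_,
        character(1L))
    mrna_gene <- parent1(mrna)
    ## primary transcript: longest mRNA per gene
    keep <- unlist(lapply(split(seq_along(mrna), mrna_gene), function(i)
        i[which.max(BiocGenerics::width(mrna)[i])]), use.names = FALSE)
    mrna <- mrna[keep]
    tx2gene <- stats::setNames(parent1(mrna), mrna$ID)
    segGene <- function(seg) {
        p <- parent1(seg)
        g <- ifelse(p %in% names(tx2gene), tx2gene[p],
                    ifelse(p %in% names(gene_gr), p, NA_character_))
        sel <- !is.na(g)
        GenomicRanges::split(seg[sel], g[sel])
    }
    exons <- segGene(gff[ty == "exon"])
    cds <- segGene(gff[ty == "CDS"])
    utrs <- segGene(gff[ty %in% c("five_prime_UTR", "three_prime_UTR",
                                  "UTR")])
    keep_cols <- function(grl, cols) GenomicRanges::GRangesList(
        lapply(grl, function(g) {
            mc <- S4Vectors::mcols(g)
            S4Vectors::mcols(g) <- mc[intersect(cols, colnames(mc))]
            g
        }))
    GenomeAnnotation(genes = gene_gr[order(
                         as.character(GenomeInfoDb::seqnames(gene_gr)),
                         BiocGenerics::start(gene_gr))],
                     exons = keep_cols(exons, character()),
                     cds = keep_cols(cds, "phase"),
                     utrs = keep_cols(utrs, character()))
}

#' Write a GenomeAnnotation as GFF3
#'
#' One gene and one mRNA row per gene, then exon, CDS (with phase) and
#' UTR rows. Output re-reads identically through
#' \code{\link{readAnnotation}}.
#'
#' @param anno a \linkS4class{GenomeAnnotation}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeAnnotationGff3 <- function(anno, path) {
    out <- c("##gff-version 3")
    fmt <- function(chrom, src, type, start, end, strand, phase, attrs)
        paste(chrom, src, type, start, end, ".", strand, phase, attrs,
              sep = "\t")
    g <- genes(anno)
    for (gid in names(g)) {
        gr <- g[gid]
        ch <- as.character(GenomeInfoDb::seqnames(gr))
        st <- as.character(BiocGenerics::strand(gr))
        if (st == "*") st <- "+"
        tid <- paste0(gid, ".t1")
        out <- c(out,
                 fmt(ch, "panQTL", "gene", BiocGenerics::start(gr),
                     BiocGenerics::end(gr), st, ".",
                     paste0("ID=", gid)),
                 fmt(ch, "panQTL", "mRNA", BiocGenerics::start(gr),
                     BiocGenerics::end(gr), st, ".",
                     paste0("ID=", tid, ";Parent=", gid)))
        emit <- function(segs, type, with_phase = FALSE) {
            if (is.null(segs)) return(character())
            ph <- if (with_phase && "phase" %in%
                      colnames(S4Vectors::mcols(segs)))
                S4Vectors::mcols(segs)$phase else
                rep(if (with_phase) 0L else ".", length(segs))
            vapply(seq_along(segs), function(i)
                fmt(ch, "panQTL", type, BiocGenerics::start(segs)[i],
                    BiocGenerics::end(segs)[i], st,
                    as.character(ph[i]),
                    paste0("ID=", tid, ".", tolower(type), i,
                           ";Parent=", tid)),
                character(1L))
        }
        ex <- exonsBy(anno)[[gid]]
        cd <- cdsBy(anno)[[gid]]
        ut <- utrsBy(anno)[[gid]]
        out <- c(out, emit(ex, "exon"), emit(cd, "CDS", TRUE))
        if (!is.null(ut) && length(ut)) {
            ## label UTR sides relative to CDS in genomic coordinates
            side <- ifelse(BiocGenerics::end(ut) <
                               min(BiocGenerics::start(cd)),
                           "left", "right")
            type5 <- if (st == "+") "left" else "right"
            ty <- ifelse(side == type5, "five_prime_UTR",
                         "three_prime_UTR")
            for (i in seq_along(ut))
                out <- c(out, fmt(ch, "panQTL", ty[i],
                                  BiocGenerics::start(ut)[i],
                                  BiocGenerics::end(ut)[i], st, ".",
                                  paste0("ID=", tid, ".utr", i,
                                         ";Parent=", tid)))
        }
    }
    writeLines(out, path)
    invisible(path)
}
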