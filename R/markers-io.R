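## VCF I/O and tabular inputs for marker sets.

## Light structural validation so malformed input is reported with its line
## number before handing the file to the VariantAnnotation parser.
.validateVcfLines <- function(path) {
    lines <- readLines(path, warn = FALSE)
    body <- which(!startsWith(lines, "#") & nzchar(lines))
    hdr <- grep("^#CHROM\t", lines)
    if (!length(hdr))
        stop("malformed VCF: no #CHROM header line in '", path, "'")
    ncol_hdr <- length(strsplit(lines[hdr[1L]], "\t", fixed = TRUE)[[1L]])
    if (ncol_hdr < 10L)
        stop("empty panel: VCF '", path, "' has no sample columns")
    for (i in body) {
        f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
        if (length(f) != ncol_hdr)
            stop("malformed VCF line ", i, ": expected ", ncol_hdr,
                 " fields, found ", length(f))
        if (is.na(suppressWarnings(as.integer(f[2L]))))
            stop("malformed VCF line ", i, ": POS '", f[2L],
                 "' is not an integer")
    }
    invisible(TRUE)
}

## GT string -> count of non-reference alleles. Half-missing genotypes
## (e.g. "0/.") are treated as fully missing: no fractional dosages.
.gtToDosage <- function(gt) {
    gt <- sub(":.*", "", gt)
    parts <- strsplit(gt, "[/|]")
    vapply(parts, function(a) {
        if (length(a) == 0L || any(a == "." | a == ""))
            return(NA_integer_)
        sum(as.integer(a) > 0L)
    }, integer(1L))
}

#' Read a marker set from VCF
#'
#' Parses a VCF 4.x file (plain or bgzipped) into a
#' \linkS4class{MarkerSet}. Multi-allelic records are retained but flagged
#' (\code{marker_type == "multi"}) for removal by
#' \code{\link{filterBiallelic}}. Phased and unphased genotypes are both
#' mapped to dosages (count of non-reference alleles); genotypes with any
#' missing allele become \code{NA}.
#'
#' @param path path to a VCF file with GT fields for at least one sample.
#' @return A \linkS4class{MarkerSet}.
#' @examples
#' v <- system.file("extdata", "toy.vcf", package = "panQTL")
#' if (nzchar(v)) readMarkerVcf(v)
#' @export
readMarkerVcf <- function(path) {
    if (!file.exists(path)) stop("VCF file not found: ", path)
    if (!grepl("\\.gz$", path)) .validateVcfLines(path)
    vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
    if (ncol(vcf) == 0L)
        stop("empty panel: VCF '", path, "' has no samples")
    rr <- SummarizedExperiment::rowRanges(vcf)
    alt <- VariantAnnotation::alt(vcf)
    alt_chr <- vapply(as.list(alt), function(a)
        paste(as.character(a), collapse = ","), character(1L))
    gt <- VariantAnnotation::geno(vcf)$GT
    if (is.null(gt)) stop("VCF '", path, "' carries no GT genotype field")
    dos <- matrix(.gtToDosage(gt), nrow = nrow(gt),
                  dimnames = dimnames(gt))
    MarkerSet(dos,
              chrom = as.character(GenomeInfoDb::seqnames(rr)),
              pos = BiocGenerics::start(rr),
              ref = as.character(VariantAnnotation::ref(vcf)),
              alt = alt_chr,
              id = names(rr))
}

#' Write a marker set to VCF
#'
#' Emits a minimal VCF 4.2 file with a GT field encoding the stored
#' dosages (0/0, 0/1, 1/1, or ./.). Round-trips through
#' \code{\link{readMarkerVcf}}. Multi-allelic dosage encodings are lossy by
#' construction (a dosage does not record which alternate allele); they are
#' written against the first alternate allele.
#'
#' @param ms a \linkS4class{MarkerSet}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeMarkerVcf <- function(ms, path) {
    d <- dosages(ms)
    gt <- matrix("./.", nrow(d), ncol(d))
    gt[!is.na(d) & d == 0L] <- "0/0"
    gt[!is.na(d) & d == 1L] <- "0/1"
    gt[!is.na(d) & d == 2L] <- "1/1"
    rr <- SummarizedExperiment::rowRanges(ms)
    chroms <- unique(as.character(GenomeInfoDb::seqnames(rr)))
    hdr <- c("##fileformat=VCFv4.2",
             paste0("##contig=<ID=", chroms, ">"),
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", accessionIds(ms)), collapse = "\t"))
    body <- paste(as.character(GenomeInfoDb::seqnames(rr)),
                  BiocGenerics::start(rr), markerIds(ms),
                  refAllele(ms), altAllele(ms), ".", "PASS", ".", "GT",
                  apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
    writeLines(c(hdr, if (nrow(d)) body), path)
    invisible(path)
}

#' Read and write phenotype tables
#'
#' Plain delimited text: first column the accession id, then one numeric
#' column per trait/location/nitrogen combination, named like
#' \code{18:1_SD_HN} (trait, location code, nitrogen level).
#'
#' @param path a file path.
#' @return \code{readPhenotypes}: a data.frame with rownames set to
#'   accession ids and one numeric column per trait combination.
#' @export
readPhenotypes <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 2L)
        stop("phenotype table needs an accession column and >=1 trait")
    rownames(df) <- as.character(df[[1L]])
    df[[1L]] <- NULL
    for (j in seq_along(df)) df[[j]] <- as.numeric(df[[j]])
    df
}

#' @rdname readPhenotypes
#' @param pheno data.frame of traits with accession ids as rownames.
#' @export
writePhenotypes <- function(pheno, path) {
    out <- cbind(accession_id = rownames(pheno), pheno)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a marker list table
#'
#' TSV with at least columns \code{id}, \code{chrom}, \code{pos};
#' optionally \code{trait}, \code{effect}, \code{maf}, \code{pve}. Used as
#' input to region construction and haplotype scoring.
#'
#' @param path TSV file path.
#' @return data.frame sorted by (chrom, pos).
#' @export
readMarkerTable <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            check.names = FALSE)
    need <- c("id", "chrom", "pos")
    if (!all(need %in% colnames(df)))
        stop("marker table must have columns id, chrom, pos")
    df$pos <- as.integer(df$pos)
    df[order(df$chrom, df$pos), , drop = FALSE]
}
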