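## Synthetic data with planted ground truth: reference genome +
## annotation, pangenome members with planted mutation classes, marker
## panels with LD-block structure, and phenotypes with planted additive
## QTL effects. Everything is reproducible per seed.

.BASES <- c("A", "C", "G", "T")
.STOPS <- c("TAA", "TAG", "TGA")
.SENSE_CODONS <- {
    all3 <- apply(expand.grid(.BASES, .BASES, .BASES), 1L, paste,
                  collapse = "")
    setdiff(all3, .STOPS)
}
.MUTATION_CLASSES <- c("nonsyn_sub", "syn_sub", "frameshift_indel",
                       "inframe_indel", "utr_sub", "intron_sub",
                       "flank_sub", "gene_deletion", "none")
.CLASS_TO_PAIRWISE <- c(nonsyn_sub = "PROTEIN_DIFF",
                        syn_sub = "SILENT_CDS",
                        frameshift_indel = "PROTEIN_DIFF",
                        inframe_indel = "PROTEIN_DIFF",
                        utr_sub = "NONCODING_ONLY",
                        intron_sub = "NONCODING_ONLY",
                        flank_sub = "NONCODING_ONLY",
                        gene_deletion = "NO_MATCH",
                        none = "NO_DIFF")

#' Planted mutation classes and their implied classifications
#'
#' \code{mutationClasses()} lists the nine classes the pangenome
#' generator can plant; \code{impliedClassification()} maps each class to
#' the pairwise classification the alignment classifier must recover.
#' @return character vectors.
#' @export
mutationClasses <- function() .MUTATION_CLASSES

#' @rdname mutationClasses
#' @param classes character vector of mutation class names.
#' @export
impliedClassification <- function(classes) {
    bad <- setdiff(classes, .MUTATION_CLASSES)
    if (length(bad)) stop("unknown mutation class(es): ",
                          paste(bad, collapse = ", "))
    unname(.CLASS_TO_PAIRWISE[classes])
}

.randSeq <- function(n) paste(sample(.BASES, n, replace = TRUE),
                              collapse = "")

## no.init.codon: otherwise alternative initiators (TTG, CTG) translate
## to M as a first codon and break synonymy checks
.aa <- function(codon) as.character(
    Biostrings::translate(Biostrings::DNAString(codon),
                          no.init.codon = TRUE))

## Build one gene in local (transcript-forward) coordinates.
.buildGene <- function(nExons, nCodons, utr5Len, utr3Len, intronLens) {
    cds <- paste0("ATG",
                  paste(sample(.SENSE_CODONS, nCodons - 2L,
                               replace = TRUE), collapse = ""),
                  sample(.STOPS, 1L))
    exonic <- paste0(.randSeq(utr5Len), cds, .randSeq(utr3Len))
    elen <- nchar(exonic)
    cds_lo <- utr5Len + 1L; cds_hi <- utr5Len + nchar(cds)
    ## exon split points in exonic space (each exon >= 30 bp)
    if (nExons > 1L) {
        repeat {
            cuts <- sort(sample(seq(30L, elen - 30L), nExons - 1L))
            if (all(diff(c(0L, cuts, elen)) >= 30L)) break
        }
    } else cuts <- integer(0L)
    ex_lo <- c(1L, cuts + 1L); ex_hi <- c(cuts, elen)
    shift <- cumsum(c(0L, intronLens))  # intron bases before each exon
    intr <- vapply(intronLens, function(L)
        paste0("GT", .randSeq(L - 4L), "AG"), character(1L))
    seq_local <- paste0(paste0(
        vapply(seq_len(nExons), function(i)
            paste0(substr(exonic, ex_lo[i], ex_hi[i]),
                   if (i < nExons) intr[i] else ""), character(1L))),
        collapse = "")
    toLocal <- function(lo, hi) {  # exonic interval -> local segments
        segs <- NULL
        for (i in seq_len(nExons)) {
            a <- max(lo, ex_lo[i]); b <- min(hi, ex_hi[i])
            if (a <= b)
                segs <- rbind(segs, c(a + shift[i], b + shift[i]))
        }
        segs
    }
    cds_segs <- toLocal(cds_lo, cds_hi)
    utr_segs <- rbind(if (utr5Len > 0L) toLocal(1L, utr5Len),
                      if (utr3Len > 0L) toLocal(cds_hi + 1L, elen))
    exon_segs <- cbind(ex_lo + shift[seq_len(nExons)],
                       ex_hi + shift[seq_len(nExons)])
    ## GFF phase per CDS segment
    lens <- cds_segs[, 2L] - cds_segs[, 1L] + 1L
    phase <- (3L - (cumsum(c(0L, lens))[seq_along(lens)] %% 3L)) %% 3L
    list(seq = seq_local, len = nchar(seq_local), exons = exon_segs,
         cds = cds_segs, utrs = utr_segs, phase = phase)
}

#' Generate a reference genome with annotated genes
#'
#' Uniform-random ACGT chromosomes carrying non-overlapping genes, each
#' with a 5' UTR, 2-4 exons, canonical GT..AG introns, a CDS starting at
#' ATG, ending at a stop codon, divisible by 3, with no internal stop,
#' and a 3' UTR. Strand is random. Byte-identical output for identical
#' seeds.
#'
#' @param nChrom number of chromosomes.
#' @param chromLen chromosome length in bp.
#' @param nGenes total genes (packed round-robin across chromosomes).
#' @param seed RNG seed.
#' @param nCodonRange CDS length range in codons (default 120-200).
#' @param intergenic min/max intergenic gap in bp (default 1500-2500;
#'   also keeps planted flank edits of neighbouring genes out of each
#'   other's windows).
#' @return list: \code{genome} (named DNAStringSet), \code{annotation}
#'   (\linkS4class{GenomeAnnotation}), \code{gene_ids}.
#' @export
makeReference <- function(nChrom = 2L, chromLen = 50000L, nGenes = 10L,
                          seed = 1L, nCodonRange = c(120L, 200L),
                          intergenic = c(1500L, 2500L)) {
    if (nGenes * 3000 > nChrom * chromLen)
        stop("capacity error: genes do not fit (need ~3 kb per gene)")
    set.seed(seed)
    per_chrom <- diff(round(seq(0L, nGenes, length.out = nChrom + 1L)))
    chrom_seqs <- character(nChrom)
    gene_rows <- list()
    gid <- 0L
    for (ci in seq_len(nChrom)) {
        cursor <- 0L
        parts <- character(0L)
        for (k in seq_len(per_chrom[ci])) {
            gid <- gid + 1L
            gap <- sample(seq(intergenic[1L], intergenic[2L]), 1L)
            gene <- .buildGene(
                nExons = sample(2:4, 1L),
                nCodons = sample(seq(nCodonRange[1L], nCodonRange[2L]),
                                 1L),
                utr5Len = sample(60:150, 1L),
                utr3Len = sample(60:150, 1L),
                intronLens = sample(80:200, 3L, replace = TRUE))
            strand <- sample(c("+", "-"), 1L)
            start <- cursor + gap + 1L
            if (start + gene$len - 1L > chromLen)
                stop("capacity error: chromosome ", ci, " overflow")
            flip <- function(segs) {  # local -> genomic coordinates
                if (strand == "+") cbind(start + segs[, 1L] - 1L,
                                         start + segs[, 2L] - 1L)
                else cbind(start + gene$len - segs[, 2L],
                           start + gene$len - segs[, 1L])
            }
            gseq <- if (strand == "+") gene$seq else
                as.character(Biostrings::reverseComplement(
                    Biostrings::DNAString(gene$seq)))
            parts <- c(parts, .randSeq(gap), gseq)
            phase <- gene$phase  # travels with its segment row
            cds_g <- flip(gene$cds)
            gene_rows[[gid]] <- list(
                id = sprintf("gene%03d", gid),
                chrom = paste0("chr", ci), strand = strand,
                start = start, end = start + gene$len - 1L,
                exons = flip(gene$exons), cds = cds_g,
                cds_phase = phase, utrs = flip(gene$utrs))
            cursor <- start + gene$len - 1L
        }
        tail_len <- chromLen - cursor
        chrom_seqs[ci] <- paste0(paste(parts, collapse = ""),
                                 .randSeq(tail_len))
    }
    genome <- Biostrings::DNAStringSet(chrom_seqs)
    names(genome) <- paste0("chr", seq_len(nChrom))
    mkgr <- function(row, segs, phase = NULL) {
        gr <- GenomicRanges::GRanges(
            row$chrom,
            IRanges::IRanges(segs[, 1L], segs[, 2L]),
            strand = row$strand)
        if (!is.null(phase)) S4Vectors::mcols(gr)$phase <- phase
        gr
    }
    ids <- vapply(gene_rows, `[[`, character(1L), "id")
    ggr <- GenomicRanges::GRanges(
        vapply(gene_rows, `[[`, character(1L), "chrom"),
        IRanges::IRanges(vapply(gene_rows, `[[`, numeric(1L), "start"),
                         vapply(gene_rows, `[[`, numeric(1L), "end")),
        strand = vapply(gene_rows, `[[`, character(1L), "strand"))
    names(ggr) <- ids
    GenomeInfoDb::seqlengths(ggr) <-
        stats::setNames(rep(chromLen, nChrom), names(genome))
    anno <- GenomeAnnotation(
        genes = ggr,
        exons = GenomicRanges::GRangesList(stats::setNames(
            lapply(gene_rows, function(r) mkgr(r, r$exons)), ids)),
        cds = GenomicRanges::GRangesList(stats::setNames(
            lapply(gene_rows, function(r)
                mkgr(r, r$cds, r$cds_phase)), ids)),
        utrs = GenomicRanges::GRangesList(stats::setNames(
            lapply(gene_rows, function(r) mkgr(r, r$utrs)), ids)))
    list(genome = genome, annotation = anno, gene_ids = ids)
}

#' Write a reference bundle to disk
#'
#' @param ref list from \code{\link{makeReference}}.
#' @param dir output directory (created if needed); writes \code{ref.fa}
#'   and \code{genes.gff3}.
#' @return the directory, invisibly.
#' @export
writeReference <- function(ref, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    Biostrings::writeXStringSet(ref$genome, file.path(dir, "ref.fa"))
    writeAnnotationGff3(ref$annotation, file.path(dir, "genes.gff3"))
    invisible(dir)
}

## Genomic positions of a gene's CDS in translation order, with the
## transcript-sense base at each (for strand-aware codon edits).
.cdsMap <- function(ref, geneId) {
    anno <- ref$annotation
    cd <- cdsBy(anno)[[geneId]]
    cd <- cd[order(BiocGenerics::start(cd))]
    strand <- as.character(BiocGenerics::strand(genes(anno)[geneId]))
    chrom <- as.character(GenomeInfoDb::seqnames(genes(anno)[geneId]))
    gpos <- unlist(lapply(seq_along(cd), function(i)
        seq(BiocGenerics::start(cd)[i], BiocGenerics::end(cd)[i])))
    base_fwd <- unlist(strsplit(vapply(seq_along(cd), function(i)
        as.character(Biostrings::subseq(
            ref$genome[[chrom]], BiocGenerics::start(cd)[i],
            BiocGenerics::end(cd)[i])), character(1L)), "",
        fixed = TRUE))
    if (strand == "-") {
        gpos <- rev(gpos)
        base_tx <- unname(rev(.COMPLEMENT[base_fwd]))
    } else base_tx <- base_fwd
    list(chrom = chrom, strand = strand, gpos = gpos, base = base_tx)
}

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

## Choose one edit (forward-strand range + replacement) for a gene and
## mutation class. Returns list(at = IRanges, value = character) or NULL
## for class "none".
.planEdit <- function(ref, geneId, class, flankDist = 100L) {
    anno <- ref$annotation
    gr <- genes(anno)[geneId]
    chrom <- as.character(GenomeInfoDb::seqnames(gr))
    strand <- as.character(BiocGenerics::strand(gr))
    gs <- BiocGenerics::start(gr); ge <- BiocGenerics::end(gr)
    chromSeq <- ref$genome[[chrom]]
    baseAt <- function(p) as.character(Biostrings::subseq(chromSeq, p, p))
    subAt <- function(p, newFwd)
        list(chrom = chrom, at = IRanges::IRanges(p, p), value = newFwd)
    randOther <- function(b) sample(setdiff(.BASES, b), 1L)
    if (class == "none") return(NULL)
    if (class == "gene_deletion")
        return(list(chrom = chrom, at = IRanges::IRanges(gs, ge),
                    value = ""))
    if (class %in% c("syn_sub", "nonsyn_sub")) {
        map <- .cdsMap(ref, geneId)
        ncod <- length(map$gpos) %/% 3L
        for (try in seq_len(100L)) {
            ci <- sample(seq(2L, ncod - 1L), 1L)  # spare start/stop
            idx <- (ci - 1L) * 3L + 1:3
            codon <- paste(map$base[idx], collapse = "")
            pos_in <- sample(1:3, 1L)
            old <- substr(codon, pos_in, pos_in)
            new <- randOther(old)
            cand <- codon
            substr(cand, pos_in, pos_in) <- new
            if (cand %in% .STOPS) next
            same <- identical(.aa(codon), .aa(cand))
            if ((class == "syn_sub") == same) {
                p <- map$gpos[idx[pos_in]]
                newFwd <- if (strand == "-") .COMPLEMENT[[new]] else new
                return(subAt(p, newFwd))
            }
        }
        stop("planning error: no ", class, " available in gene ",
             geneId, " after 100 draws")
    }
    if (class %in% c("frameshift_indel", "inframe_indel")) {
        cd <- cdsBy(anno)[[geneId]]
        wi <- which.max(BiocGenerics::width(cd))
        a <- BiocGenerics::start(cd)[wi]; b <- BiocGenerics::end(cd)[wi]
        p <- (a + b) %/% 2L
        ins_len <- if (class == "inframe_indel") 3L else
            sample(1:2, 1L)
        if (stats::runif(1) < 0.5) {  # insertion before p
            return(list(chrom = chrom,
                        at = IRanges::IRanges(p, width = 0L),
                        value = .randSeq(ins_len)))
        }
        return(list(chrom = chrom,  # deletion of ins_len bases
                    at = IRanges::IRanges(p, p + ins_len - 1L),
                    value = ""))
    }
    if (class == "utr_sub") {
        ut <- utrsBy(anno)[[geneId]]
        wi <- which.max(BiocGenerics::width(ut))
        a <- BiocGenerics::start(ut)[wi] + 2L
        b <- BiocGenerics::end(ut)[wi] - 2L
        p <- sample(seq(a, b), 1L)
        return(subAt(p, randOther(baseAt(p))))
    }
    if (class == "intron_sub") {
        ex <- exonsBy(anno)[[geneId]]
        introns <- GenomicRanges::setdiff(gr, ex, ignore.strand = TRUE)
        if (!length(introns))
            stop("planning error: gene ", geneId, " has no intron")
        wi <- which.max(BiocGenerics::width(introns))
        a <- BiocGenerics::start(introns)[wi] + 10L
        b <- BiocGenerics::end(introns)[wi] - 10L
        p <- sample(seq(a, b), 1L)
        return(subAt(p, randOther(baseAt(p))))
    }
    if (class == "flank_sub") {
        side <- sample(c("left", "right"), 1L)
        p <- if (side == "left")
            sample(seq(max(1L, gs - flankDist), gs - 5L), 1L)
        else sample(seq(ge + 5L, min(length(chromSeq),
                                     ge + flankDist)), 1L)
        return(subAt(p, randOther(baseAt(p))))
    }
    stop("unknown mutation class: ", class)
}

#' Generate a pangenome with planted mutation classes
#'
#' Each member genome is the reference with one planted edit per
#' (gene, member) cell of the plan. Synonymous substitutions are verified
#' against the codon table at planning time; gene deletions remove the
#' full gene span. The returned truth table records the pairwise
#' classification each planted class implies under the classification
#' cascade, and the per-gene category implied by
#' \code{\link{categorizeGene}}.
#'
#' @param ref reference bundle from \code{\link{makeReference}}.
#' @param plan data.frame with columns \code{member}, \code{gene_id},
#'   \code{class} (values from \code{\link{mutationClasses}()}), or the
#'   output of \code{\link{planPangenome}}. Genes absent from a member's
#'   rows are left unedited.
#' @param seed RNG seed.
#' @param flankDist flank edits are placed within this many bp of the
#'   gene span (default 100; keep below the extraction flank so they are
#'   visible to the classifier).
#' @return list: \code{members} (named list of DNAStringSet),
#'   \code{truth} (data.frame member, gene_id, class,
#'   expected_pairwise), \code{gene_truth} (data.frame gene_id,
#'   expected_category).
#' @export
makePangenome <- function(ref, plan, seed = 1L, flankDist = 100L) {
    stopifnot(all(c("member", "gene_id", "class") %in% colnames(plan)))
    bad <- setdiff(unique(plan$class), .MUTATION_CLASSES)
    if (length(bad)) stop("unknown mutation class(es): ",
                          paste(bad, collapse = ", "))
    set.seed(seed)
    members <- list()
    for (mb in unique(plan$member)) {
        rows <- plan[plan$member == mb, , drop = FALSE]
        edits <- list()
        for (i in seq_len(nrow(rows))) {
            e <- .planEdit(ref, rows$gene_id[i], rows$class[i],
                           flankDist)
            if (!is.null(e)) edits[[length(edits) + 1L]] <- e
        }
        genome <- ref$genome
        if (length(edits)) {
            bychrom <- split(edits, vapply(edits, `[[`, character(1L),
                                           "chrom"))
            for (ch in names(bychrom)) {
                at <- do.call(c, lapply(bychrom[[ch]], `[[`, "at"))
                val <- Biostrings::DNAStringSet(
                    vapply(bychrom[[ch]], `[[`, character(1L), "value"))
                genome[[ch]] <- Biostrings::replaceAt(
                    genome[[ch]], at, val)
            }
        }
        members[[as.character(mb)]] <- genome
    }
    truth <- data.frame(member = as.character(plan$member),
                        gene_id = plan$gene_id, class = plan$class,
                        expected_pairwise =
                            impliedClassification(plan$class),
                        stringsAsFactors = FALSE)
    gene_truth <- do.call(rbind, lapply(
        split(truth, truth$gene_id), function(tt)
            data.frame(gene_id = tt$gene_id[1L],
                       expected_category =
                           categorizeGene(tt$expected_pairwise),
                       stringsAsFactors = FALSE)))
    rownames(gene_truth) <- NULL
    list(members = members, truth = truth, gene_truth = gene_truth)
}

#' Draw a random member-by-gene mutation plan
#'
#' Assigns each (member, gene) cell a class sampled from \code{classes},
#' guaranteeing every class appears at least once when the plan is large
#' enough.
#'
#' @param ref reference bundle.
#' @param nMembers number of pangenome members.
#' @param classes classes to sample from (default all nine).
#' @param seed RNG seed.
#' @return data.frame member, gene_id, class.
#' @export
planPangenome <- function(ref, nMembers = 5L,
                          classes = mutationClasses(), seed = 1L) {
    set.seed(seed)
    grid <- expand.grid(member = paste0("member", seq_len(nMembers)),
                        gene_id = ref$gene_ids,
                        KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
    n <- nrow(grid)
    cls <- sample(classes, n, replace = TRUE)
    if (n >= length(classes))  # guarantee coverage of every class
        cls[sample.int(n, length(classes))] <- sample(classes)
    grid$class <- cls
    grid
}

#' Generate a marker panel with LD-block structure
#'
#' Markers are placed uniformly along the reference; within each block of
#' \code{blockLen} bp, genotypes are copied from a shared latent
#' haplotype pair (perfect LD) with per-marker flip noise; blocks are
#' independent. Missing entries are masked at \code{missingRate}.
#'
#' @param ref reference bundle from \code{\link{makeReference}}.
#' @param nAccessions,nMarkers panel dimensions.
#' @param blockLen LD block length in bp (default 25000).
#' @param mafRange latent allele-frequency range (default 0.1-0.4).
#' @param missingRate fraction of masked genotypes (default 0).
#' @param flipNoise per-marker, per-gamete probability of flipping the
#'   latent allele (default 0.02).
#' @param indelFrac fraction of markers written as indels (default 0.3;
#'   the panel mimics separate SNP and indel discovery).
#' @param multiallelicFrac fraction of multi-allelic records
#'   (default 0).
#' @param seed RNG seed.
#' @return a \linkS4class{MarkerSet} with attribute \code{truth}: a
#'   data.frame of per-marker block id and latent block frequency.
#' @export
makePopulation <- function(ref, nAccessions = 200L, nMarkers = 300L,
                           blockLen = 25000L, mafRange = c(0.1, 0.4),
                           missingRate = 0, flipNoise = 0.02,
                           indelFrac = 0.3, multiallelicFrac = 0,
                           seed = 1L) {
    stopifnot(missingRate >= 0, missingRate <= 1,
              flipNoise >= 0, flipNoise <= 1)
    set.seed(seed)
    lens <- vapply(ref$genome, length, integer(1L))
    n_per <- round(nMarkers * lens / sum(lens))
    n_per[1L] <- nMarkers - sum(n_per[-1L])
    chrom <- rep(names(lens), n_per)
    pos <- unlist(lapply(seq_along(lens), function(i)
        sort(sample.int(lens[i], n_per[i]))), use.names = FALSE)
    block <- paste0(chrom, "_b", (pos - 1L) %/% blockLen)
    ublock <- unique(block)
    bfreq <- stats::setNames(stats::runif(length(ublock), mafRange[1L],
                                          mafRange[2L]), ublock)
    ## two latent gametes per accession per block
    lat <- lapply(ublock, function(b)
        matrix(stats::rbinom(2L * nAccessions, 1L, bfreq[b]),
               nrow = 2L))
    names(lat) <- ublock
    dos <- matrix(0L, nMarkers, nAccessions)
    for (i in seq_len(nMarkers)) {
        g <- lat[[block[i]]]
        flip <- matrix(stats::rbinom(length(g), 1L, flipNoise),
                       nrow = 2L)
        al <- (g + flip) %% 2L
        dos[i, ] <- colSums(al)
    }
    if (missingRate > 0) {
        mask <- matrix(stats::runif(length(dos)) < missingRate,
                       nrow(dos))
        dos[mask] <- NA_integer_
    }
    refb <- vapply(seq_len(nMarkers), function(i) as.character(
        Biostrings::subseq(ref$genome[[chrom[i]]], pos[i], pos[i])),
        character(1L))
    is_multi <- stats::runif(nMarkers) < multiallelicFrac
    is_indel <- !is_multi & stats::runif(nMarkers) < indelFrac
    alt <- character(nMarkers)
    for (i in seq_len(nMarkers)) {
        others <- setdiff(.BASES, refb[i])
        alt[i] <- if (is_multi[i])
            paste(sample(others, 2L), collapse = ",")
        else if (is_indel[i]) paste0(refb[i], .randSeq(sample(1:3, 1L)))
        else sample(others, 1L)
    }
    ids <- sprintf("mk%04d", seq_len(nMarkers))
    ms <- MarkerSet(dos, chrom, pos, refb, alt, id = ids)
    o <- order(chrom, pos)
    attr(ms, "truth") <- data.frame(id = ids[o], block = block[o],
                                    block_freq = unname(bfreq[block[o]]),
                                    stringsAsFactors = FALSE)
    ms
}

#' Generate phenotypes with planted additive QTL effects
#'
#' Trait value = sum over QTL markers of (effect x dosage) + Gaussian
#' noise scaled so the genetic variance fraction equals
#' \code{heritability}. Missing dosages contribute 0. Columns are named
#' in trait_location_nitrogen style.
#'
#' @param ms a \linkS4class{MarkerSet}.
#' @param qtlEffects named numeric vector: per-allele effect by marker
#'   id; may be empty (pure-noise traits).
#' @param heritability genetic variance fraction in (0, 1].
#' @param nTraits number of replicate trait columns (default 1).
#' @param traitNames optional column names.
#' @param seed RNG seed.
#' @return data.frame of traits, rownames = accession ids.
#' @export
makePhenotypes <- function(ms, qtlEffects = numeric(0L),
                           heritability = 0.8, nTraits = 1L,
                           traitNames = NULL, seed = 1L) {
    stopifnot(heritability > 0, heritability <= 1)
    set.seed(seed)
    n <- ncol(ms)
    g <- numeric(n)
    if (length(qtlEffects)) {
        miss <- setdiff(names(qtlEffects), rownames(ms))
        if (length(miss)) stop("unknown QTL marker id(s): ",
                               paste(miss, collapse = ", "))
        d <- dosages(ms)[names(qtlEffects), , drop = FALSE]
        d[is.na(d)] <- 0L
        g <- as.numeric(crossprod(d, qtlEffects))
    }
    vg <- stats::var(g)
    if (length(qtlEffects) && vg == 0 && heritability < 1)
        stop("scaling error: zero genetic variance with heritability < 1")
    sd_e <- if (!length(qtlEffects)) 1 else if (heritability == 1) 0 else
        sqrt(vg * (1 - heritability) / heritability)
    if (is.null(traitNames)) {
        combos <- c("18:1_SD_HN", "18:1_SD_LN", "18:1_BZ_NA",
                    "18:1_PM_HN", "18:2_PM_LN")
        traitNames <- rep_len(combos, nTraits)
        if (anyDuplicated(traitNames))
            traitNames <- paste0(traitNames, "_", seq_len(nTraits))
    }
    out <- as.data.frame(vapply(seq_len(nTraits), function(j)
        g + stats::rnorm(n, 0, sd_e), numeric(n)))
    colnames(out) <- traitNames
    rownames(out) <- accessionIds(ms)
    out
}

#' Write a full synthetic fixture set
#'
#' Produces \code{ref.fa}, \code{genes.gff3}, \code{members/*.fa},
#' \code{panel.vcf}, \code{pheno.tsv} and \code{truth.json} under
#' \code{dir}, using either a small single-purpose preset or explicit
#' parameters.
#'
#' @param dir output directory.
#' @param seed RNG seed.
#' @param preset \code{"small"} (2 chromosomes, 10 genes, 5 members,
#'   100 accessions) for quick end-to-end runs.
#' @return invisibly, a list with the in-memory objects.
#' @export
simulateFixtures <- function(dir, seed = 42L, preset = "small") {
    stopifnot(preset == "small")
    ref <- makeReference(nChrom = 2L, chromLen = 40000L, nGenes = 10L,
                         seed = seed)
    writeReference(ref, dir)
    plan <- planPangenome(ref, nMembers = 5L, seed = seed + 1L)
    pg <- makePangenome(ref, plan, seed = seed + 2L)
    mdir <- file.path(dir, "members")
    if (!dir.exists(mdir)) dir.create(mdir)
    for (mb in names(pg$members))
        Biostrings::writeXStringSet(pg$members[[mb]],
                                    file.path(mdir,
                                              paste0(mb, ".fa")))
    ms <- makePopulation(ref, nAccessions = 100L, nMarkers = 150L,
                         blockLen = 10000L, missingRate = 0.02,
                         seed = seed + 3L)
    writeMarkerVcf(ms, file.path(dir, "panel.vcf"))
    eff <- stats::setNames(c(1, -0.8), rownames(ms)[c(10L, 60L)])
    ph <- makePhenotypes(ms, eff, heritability = 0.8, seed = seed + 4L)
    writePhenotypes(ph, file.path(dir, "pheno.tsv"))
    jsonlite::write_json(
        list(truth = pg$truth, gene_truth = pg$gene_truth,
             qtl_effects = as.list(eff)),
        file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
    invisible(list(ref = ref, pangenome = pg, markers = ms,
                   phenotypes = ph, qtl_effects = eff))
}
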