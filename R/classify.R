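## The classification cascade: per-member alignment verdicts and the
## five-way gene categories, plus the region-level driver that runs
## extract -> search -> align -> classify -> categorize across a
## pangenome.

.isRealBase <- function(x) x %in% c("A", "C", "G", "T")

#' Classify a reference-vs-member alignment
#'
#' Decision cascade over the labeled alignment columns:
#' \enumerate{
#'   \item any CDS-column change that alters the translated protein --- a
#'     non-synonymous substitution, any CDS indel (frameshift or in-frame
#'     residue insertion/deletion), a gained or lost stop or start ---
#'     gives \code{PROTEIN_DIFF};
#'   \item otherwise any CDS nucleotide difference gives
#'     \code{SILENT_CDS};
#'   \item otherwise any difference in non-coding columns (UTR, intron,
#'     flank) gives \code{NONCODING_ONLY};
#'   \item otherwise \code{NO_DIFF}.
#' }
#' \code{NO_MATCH} is assigned upstream when the homology search finds no
#' adequate hit. Ambiguous (non-ACGT) bases never trigger a difference by
#' themselves.
#'
#' @param aln a \code{pairAlignment} from \code{\link{alignPair}} whose
#'   columns carry feature labels.
#' @return a single character value from \code{\link{pairwiseClasses}()}.
#' @export
classifyAlignment <- function(aln) {
    stopifnot(inherits(aln, "pairAlignment"))
    ra <- strsplit(aln$ref_aln, "", fixed = TRUE)[[1L]]
    ma <- strsplit(aln$member_aln, "", fixed = TRUE)[[1L]]
    lab <- aln$col_label
    if (length(lab) != length(ra) || anyNA(lab))
        stop("internal-consistency error: unlabeled alignment column")
    is_cds <- lab == "cds"
    gapdiff <- (ra == "-") != (ma == "-")
    subdiff <- ra != "-" & ma != "-" & ra != ma &
        .isRealBase(ra) & .isRealBase(ma)
    if (any(gapdiff[is_cds]))
        return("PROTEIN_DIFF")  # any CDS indel alters the protein
    if (any(subdiff[is_cds])) {
        ref_cds <- paste(ra[is_cds & ra != "-"], collapse = "")
        mem_cds <- paste(ma[is_cds & ma != "-"], collapse = "")
        ref_aa <- .translateCds(ref_cds)
        mem_aa <- .translateCds(mem_cds)
        if (!identical(ref_aa, mem_aa)) return("PROTEIN_DIFF")
        return("SILENT_CDS")
    }
    if (any(gapdiff[!is_cds] | subdiff[!is_cds]))
        return("NONCODING_ONLY")
    "NO_DIFF"
}

.translateCds <- function(s) {
    n <- nchar(s)
    if (n == 0L) return("")
    s <- substr(s, 1L, n - n %% 3L)  # tolerate off-frame real annotations
    ## no.init.codon so a mutated start codon reads as its literal amino
    ## acid and start-loss surfaces as a protein difference
    as.character(Biostrings::translate(Biostrings::DNAString(s),
                                       if.fuzzy.codon = "X",
                                       no.init.codon = TRUE))
}

#' Aggregate per-member classifications into a gene category
#'
#' With P the number of members showing protein differences: P >= 4 gives
#' \code{PROTEIN_DIFF_4PLUS}; 1 <= P <= 3 gives \code{PROTEIN_DIFF_1TO3};
#' otherwise any silent CDS difference gives \code{SILENT_CDS}; otherwise
#' any non-coding-only difference gives \code{NONCODING_ONLY}; otherwise
#' \code{NO_MATCH_OR_NO_DIFF}. The categories are conditionally
#' exclusive, ordered from more differences to fewer, and partition the
#' gene set.
#'
#' @param classifications character vector of per-member values from
#'   \code{\link{pairwiseClasses}()} (named by member); must be
#'   non-empty.
#' @return a single value from \code{\link{geneCategories}()}.
#' @export
categorizeGene <- function(classifications) {
    if (!length(classifications))
        stop("precondition error: no member classifications")
    bad <- setdiff(unique(classifications), .PAIRWISE_CLASSES)
    if (length(bad))
        stop("unknown classification value(s): ",
             paste(bad, collapse = ", "))
    P <- sum(classifications == "PROTEIN_DIFF")
    if (P >= 4L) return("PROTEIN_DIFF_4PLUS")
    if (P >= 1L) return("PROTEIN_DIFF_1TO3")
    if (any(classifications == "SILENT_CDS")) return("SILENT_CDS")
    if (any(classifications == "NONCODING_ONLY"))
        return("NONCODING_ONLY")
    "NO_MATCH_OR_NO_DIFF"
}

#' Count genes per category
#'
#' @param categories character vector of per-gene values from
#'   \code{\link{geneCategories}()}.
#' @return named integer vector over the five categories (sums to
#'   \code{length(categories)}).
#' @export
summarizeCategories <- function(categories) {
    out <- table(factor(categories, levels = .GENE_CATEGORIES))
    stats::setNames(as.integer(out), .GENE_CATEGORIES)
}

#' Classify every gene in every region across a pangenome
#'
#' For each gene overlapping each region, runs the full chain: extract
#' the labeled gene sequence from the reference (genomic mode: unspliced
#' gene body plus \code{flank} bases, so introns and flanks are labeled
#' non-coding; \code{mode = "mrna"} aligns the spliced mRNA with flanks
#' instead), locate the best hit in every member genome, align
#' reference-vs-member, classify the alignment, and aggregate the member
#' verdicts into one of the five gene categories. Per-gene failures are
#' logged and counted, never abort the run.
#'
#' @param regions \code{GRanges} of merged marker regions.
#' @param genome named \code{DNAStringSet} reference sequences.
#' @param annotation a \linkS4class{GenomeAnnotation}.
#' @param members named list of member \code{DNAStringSet}s (>= 1).
#' @param flank non-coding flank in bp included with each gene
#'   (default 300).
#' @param mode \code{"genomic"} (default) or \code{"mrna"}.
#' @param outDir optional directory for per-gene aligned FASTA files.
#' @param seedK,minIdentity,minCoverage passed to
#'   \code{\link{bestHitSearch}}.
#' @return list with \code{genes} (one row per gene: region index,
#'   gene_id, one column per member, category), \code{summary} (one row
#'   per region plus an \code{all_regions} row: total genes and the five
#'   category counts), and \code{failures} (character vector of messages).
#' @export
classifyRegions <- function(regions, genome, annotation, members,
                            flank = 300L, mode = c("genomic", "mrna"),
                            outDir = NULL, seedK = 15L,
                            minIdentity = 0.8, minCoverage = 0.5) {
    mode <- match.arg(mode)
    if (!length(members)) stop("zero pangenome members supplied")
    if (is.null(names(members)))
        names(members) <- paste0("member", seq_along(members))
    if (!is.null(outDir) && !dir.exists(outDir))
        dir.create(outDir, recursive = TRUE)
    gene_lists <- genesInRegion(regions, annotation)
    if (length(regions) == 1L)
        gene_lists <- IRanges::CharacterList(list(gene_lists))
    failures <- character(0L)
    rows <- list()
    for (r in seq_along(regions)) {
        for (gid in gene_lists[[r]]) {
            cls <- stats::setNames(rep(NA_character_, length(members)),
                                   names(members))
            ref <- tryCatch({
                if (mode == "genomic")
                    extractGeneSeq(annotation, gid, genome, flank)
                else extractMrna(annotation, gid, genome, flank)
            }, error = function(e) e)
            if (inherits(ref, "error")) {
                failures <- c(failures,
                              paste0(gid, ": ", conditionMessage(ref)))
                rows[[length(rows) + 1L]] <-
                    c(list(region = r, gene_id = gid), as.list(cls),
                      list(category = NA_character_))
                next
            }
            for (mb in names(members)) {
                cls[mb] <- tryCatch({
                    hit <- bestHitSearch(ref, members[[mb]],
                                         seedK = seedK,
                                         minIdentity = minIdentity,
                                         minCoverage = minCoverage)
                    if (is.null(hit)) "NO_MATCH" else {
                        mseq <- extractHitWithFlanks(hit, members[[mb]],
                                                     0L)
                        aln <- alignPair(ref, mseq)
                        if (!is.null(outDir))
                            writeAlignmentFasta(
                                aln,
                                file.path(outDir, paste0(
                                    gid, "_", mb, ".afa")),
                                names = c(paste0(gid, "_ref"),
                                          paste0(gid, "_", mb)))
                        classifyAlignment(aln)
                    }
                }, error = function(e) {
                    failures <<- c(failures, paste0(gid, "/", mb, ": ",
                                                    conditionMessage(e)))
                    NA_character_
                })
            }
            cat_val <- if (anyNA(cls)) NA_character_ else
                categorizeGene(cls)
            rows[[length(rows) + 1L]] <-
                c(list(region = r, gene_id = gid), as.list(cls),
                  list(category = cat_val))
        }
    }
    genes_df <- if (length(rows))
        do.call(rbind, lapply(rows, function(x)
            as.data.frame(x, stringsAsFactors = FALSE))) else
        data.frame(region = integer(), gene_id = character(),
                   category = character(), stringsAsFactors = FALSE)
    mkrow <- function(label, cats) {
        cnt <- summarizeCategories(cats[!is.na(cats)])
        data.frame(marker_set = label,
                   total_genes = length(cats[!is.na(cats)]),
                   t(cnt), check.names = FALSE,
                   stringsAsFactors = FALSE)
    }
    per_region <- lapply(seq_along(regions), function(r)
        mkrow(paste0("region_", r),
              genes_df$category[genes_df$region == r]))
    summary <- do.call(rbind, c(per_region,
                                list(mkrow("all_regions",
                                           genes_df$category))))
    rownames(summary) <- NULL
    list(genes = genes_df, summary = summary, failures = failures)
}
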