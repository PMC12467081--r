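# Sequence extraction, homology search, pairwise alignment, and the
# classification cascade.

test_that("mRNA extraction concatenates exons in transcript orientation", {
    # hand-built single-exon gene on a known sequence
    genome <- Biostrings::DNAStringSet(c(
        chrT = "ACGTACGTACATGGCAAGTTGACGTACGT"))
    gr <- GenomicRanges::GRanges("chrT", IRanges::IRanges(11L, 19L),
                                 strand = "+")
    names(gr) <- "g1"
    seg <- GenomicRanges::GRanges("chrT", IRanges::IRanges(11L, 19L),
                                  strand = "+")
    anno <- GenomeAnnotation(
        genes = gr,
        exons = GenomicRanges::GRangesList(g1 = seg),
        cds = GenomicRanges::GRangesList(g1 = seg))
    m <- extractMrna(anno, "g1", genome)
    expect_identical(as.character(m$seq), "ATGGCAAGT")
    # minus strand: reverse complement of the same 9-mer
    GenomicRanges::strand(anno@genes) <- "-"
    m2 <- extractMrna(anno, "g1", genome)
    expect_identical(as.character(m2$seq),
                     as.character(Biostrings::reverseComplement(
                         Biostrings::DNAString("ATGGCAAGT"))))
    # out-of-bounds features raise a coordinate error
    bad <- suppressWarnings(GenomeAnnotation(
        genes = GenomicRanges::GRanges(
            "chrT", IRanges::IRanges(25L, 40L), strand = "+",
            seqlengths = c(chrT = 29L)) |>
            stats::setNames("g2"),
        exons = GenomicRanges::GRangesList(g2 = GenomicRanges::GRanges(
            "chrT", IRanges::IRanges(25L, 40L))),
        cds = GenomicRanges::GRangesList()))
    expect_error(extractMrna(bad, "g2", genome), "coordinate")
})

test_that("spliced mRNAs drop introns and start with ATG at CDS start", {
    ref <- fixRef()
    for (g in ref$gene_ids) {
        m <- extractMrna(ref$annotation, g, ref$genome)
        expect_false("intron" %in% m$label)
        cds <- paste(strsplit(as.character(m$seq), "")[[1L]][
            m$label == "cds"], collapse = "")
        expect_identical(substr(cds, 1L, 3L), "ATG")
        expect_identical(nchar(cds) %% 3L, 0L)
        # genomic mode keeps the intron columns, same CDS
        gmode <- extractGeneSeq(ref$annotation, g, ref$genome)
        cds2 <- paste(strsplit(as.character(gmode$seq), "")[[1L]][
            gmode$label == "cds"], collapse = "")
        expect_identical(cds2, cds)
        expect_true("intron" %in% gmode$label)
    }
})

test_that("best-hit search finds planted queries on either strand", {
    set.seed(501)
    genome <- Biostrings::DNAStringSet(c(c1 = randSeq(5000L),
                                         c2 = randSeq(5000L)))
    q <- substr(as.character(genome[["c2"]]), 2001L, 3200L)
    hit <- bestHitSearch(q, genome)
    expect_identical(hit$chrom, "c2")
    expect_identical(hit$strand, "+")
    expect_identical(c(hit$start, hit$end), c(2001L, 3200L))
    expect_equal(hit$identity, 1)
    expect_equal(hit$coverage, 1)
    # minus-strand planting scores identically
    qrc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(q)))
    hit2 <- bestHitSearch(qrc, genome)
    expect_identical(hit2$strand, "-")
    expect_identical(c(hit2$start, hit2$end), c(2001L, 3200L))
    expect_equal(hit2$score, hit$score)
    # absent query (no shared 15-mers with the genome) -> no match
    q3 <- paste(rep("ACGT", 60L), collapse = "")
    expect_null(bestHitSearch(q3, Biostrings::DNAStringSet(
        c(x = paste(rep("AATT", 400L), collapse = "")))))
})

test_that("hit extraction with flanks round-trips through re-search", {
    set.seed(502)
    genome <- Biostrings::DNAStringSet(c(c1 = randSeq(6000L)))
    q <- substr(as.character(genome[["c1"]]), 1001L, 2000L)
    hit <- bestHitSearch(q, genome)
    s0 <- extractHitWithFlanks(hit, genome, 0L)
    expect_identical(as.character(s0), q)
    s100 <- extractHitWithFlanks(hit, genome, 100L)
    expect_identical(nchar(as.character(s100)), 1200L)
    hit2 <- bestHitSearch(as.character(s100), genome)
    expect_identical(c(hit2$start, hit2$end), c(901L, 2100L))
    # clipping at the contig start
    hit_edge <- data.frame(chrom = "c1", strand = "+", start = 1L,
                           end = 50L)
    expect_identical(nchar(as.character(
        extractHitWithFlanks(hit_edge, genome, 100L))), 150L)
})

test_that("global alignment matches the library oracle on short pairs", {
    set.seed(503)
    for (k in 1:40) {
        a <- randSeq(sample(5:200, 1L))
        b <- if (k %% 3L == 0L) {
            # mutated copy: substitutions and a small indel
            s <- strsplit(a, "")[[1L]]
            i <- sample(length(s), max(1L, length(s) %/% 20L))
            s[i] <- sample(c("A", "C", "G", "T"),
                           length(i), replace = TRUE)
            paste(s[-sample(length(s), 1L)], collapse = "")
        } else randSeq(sample(5:200, 1L))
        aln <- alignPair(a, b)
        expect_equal(aln$score, alignScoreOracle(a, b))
        # alignment rows reproduce the inputs when gaps are removed
        expect_identical(gsub("-", "", aln$ref_aln), a)
        expect_identical(gsub("-", "", aln$member_aln), b)
    }
})

test_that("alignments of identical or point-mutated sequences are clean", {
    s <- randSeq(300L)
    a0 <- alignPair(s, s)
    expect_identical(a0$ref_aln, s)
    expect_identical(a0$member_aln, s)
    s2 <- s
    substr(s2, 150L, 150L) <- if (substr(s, 150L, 150L) == "A") "C"
        else "A"
    a1 <- alignPair(s, s2)
    cols <- strsplit(a1$ref_aln, "")[[1L]] !=
        strsplit(a1$member_aln, "")[[1L]]
    expect_identical(sum(cols), 1L)
})

test_that("the classification cascade follows the codon table", {
    # 5' flank, one-exon CDS, 3' flank with explicit labels
    cds <- "ATGCTTCCAAGGTGA"  # M L P R *
    lab <- c(rep("flank", 6L), rep("cds", nchar(cds)),
             rep("flank", 6L))
    refseq <- paste0("AAAAAA", cds, "CCCCCC")
    mk <- function(member) {
        aln <- alignPair(refseq, member, labels = lab)
        classifyAlignment(aln)
    }
    # third-position CTT -> CTG, both Leu: silent
    expect_identical(mk(paste0("AAAAAA", "ATGCTGCCAAGGTGA", "CCCCCC")),
                     "SILENT_CDS")
    # first-position CTT -> ATT (Leu -> Ile): protein difference
    expect_identical(mk(paste0("AAAAAA", "ATGATTCCAAGGTGA", "CCCCCC")),
                     "PROTEIN_DIFF")
    # stop gained (CCA -> TGA mid-CDS)
    expect_identical(mk(paste0("AAAAAA", "ATGCTTTGAAGGTGA", "CCCCCC")),
                     "PROTEIN_DIFF")
    # flank-only substitution
    expect_identical(mk(paste0("AATAAA", cds, "CCCCCC")),
                     "NONCODING_ONLY")
    # no differences
    expect_identical(mk(refseq), "NO_DIFF")
    # 1-bp deletion inside the CDS: frameshift
    expect_identical(mk(paste0("AAAAAA", "ATGCTCCAAGGTGA", "CCCCCC")),
                     "PROTEIN_DIFF")
    # in-frame 3-bp insertion inside the CDS
    expect_identical(mk(paste0("AAAAAA", "ATGCTTAAACCAAGGTGA",
                               "CCCCCC")), "PROTEIN_DIFF")
    # silent verdicts agree with an independent codon oracle
    expect_identical(translateOracle("ATGCTTCCAAGGTGA"),
                     translateOracle("ATGCTGCCAAGGTGA"))
    expect_false(identical(translateOracle("ATGCTTCCAAGGTGA"),
                           translateOracle("ATGATTCCAAGGTGA")))
})

test_that("gene categories aggregate by the conditional-exclusion rule", {
    nm <- paste0("m", 1:12)
    allno <- stats::setNames(rep("NO_DIFF", 12L), nm)
    expect_identical(categorizeGene(allno), "NO_MATCH_OR_NO_DIFF")
    four <- allno; four[1:4] <- "PROTEIN_DIFF"
    expect_identical(categorizeGene(four), "PROTEIN_DIFF_4PLUS")
    three <- allno; three[1:3] <- "PROTEIN_DIFF"
    expect_identical(categorizeGene(three), "PROTEIN_DIFF_1TO3")
    mixed <- allno
    mixed[1:2] <- "SILENT_CDS"; mixed[3:5] <- "NONCODING_ONLY"
    expect_identical(categorizeGene(mixed), "SILENT_CDS")
    expect_identical(categorizeGene(c(a = "NO_MATCH")),
                     "NO_MATCH_OR_NO_DIFF")
    expect_error(categorizeGene(character(0L)), "precondition")
    expect_error(categorizeGene(c(a = "WAT")), "unknown")
})

test_that("classify_regions recovers planted truth and partitions genes", {
    ref <- fixRef()
    pg <- fixPangenome()
    regions <- GenomicRanges::GRanges(
        c("chr1", "chr2"), IRanges::IRanges(1L, 40000L))
    res <- classifyRegions(regions, ref$genome, ref$annotation,
                           pg$members, flank = 300L)
    expect_length(res$failures, 0L)
    # per-member verdicts match the generator truth exactly
    long <- do.call(rbind, lapply(names(pg$members), function(mb)
        data.frame(gene_id = res$genes$gene_id, member = mb,
                   obs = res$genes[[mb]])))
    m <- merge(pg$truth, long, by = c("gene_id", "member"))
    expect_identical(nrow(m), nrow(pg$truth))
    expect_identical(m$obs, m$expected_pairwise)
    # gene categories match the implied truth
    gt <- merge(pg$gene_truth, res$genes[, c("gene_id", "category")],
                by = "gene_id")
    expect_identical(gt$category, gt$expected_category)
    # the five category counts partition every summary row
    cats <- geneCategories()
    sums <- rowSums(res$summary[, cats])
    expect_equal(unname(sums), res$summary$total_genes)
    expect_error(classifyRegions(regions, ref$genome, ref$annotation,
                                 list(), flank = 300L), "zero")
})

test_that("a member identical to the reference is NO_DIFF everywhere", {
    ref <- fixRef()
    plan <- data.frame(member = "same", gene_id = ref$gene_ids,
                       class = "none")
    pg <- makePangenome(ref, plan, seed = 55L)
    expect_identical(as.character(pg$members$same),
                     as.character(ref$genome))
    regions <- GenomicRanges::GRanges(
        c("chr1", "chr2"), IRanges::IRanges(1L, 40000L))
    res <- classifyRegions(regions, ref$genome, ref$annotation,
                           pg$members, flank = 300L)
    expect_true(all(res$genes$same == "NO_DIFF"))
    # deleting every gene instead yields NO_MATCH everywhere
    plan2 <- data.frame(member = "gone", gene_id = ref$gene_ids,
                        class = "gene_deletion")
    pg2 <- makePangenome(ref, plan2, seed = 56L)
    res2 <- classifyRegions(regions, ref$genome, ref$annotation,
                            pg2$members, flank = 300L)
    expect_true(all(res2$genes$gone == "NO_MATCH"))
})

test_that("classifications are invariant under member strand flips", {
    ref <- fixRef()
    pg <- fixPangenome()
    one <- pg$members[[1L]]
    flipped <- Biostrings::reverseComplement(one)
    names(flipped) <- names(one)
    regions <- GenomicRanges::GRanges("chr1",
                                      IRanges::IRanges(1L, 40000L))
    r1 <- classifyRegions(regions, ref$genome, ref$annotation,
                          list(m = one), flank = 300L)
    r2 <- classifyRegions(regions, ref$genome, ref$annotation,
                          list(m = flipped), flank = 300L)
    expect_identical(r1$genes$m, r2$genes$m)
})
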