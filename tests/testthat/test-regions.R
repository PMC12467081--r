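# Flanked interval construction, merging, gene attachment, and
# gene-density arithmetic.

test_that("intervals are flanked and clipped at the chromosome start", {
    mk <- data.frame(id = c("a", "b"), chrom = "chr1",
                     pos = c(60000L, 20000L))
    iv <- buildIntervals(mk, flank = 50000)
    iv <- iv[order(GenomicRanges::start(iv))]
    expect_equal(GenomicRanges::start(iv), c(1L, 10000L))
    expect_equal(GenomicRanges::end(iv), c(70000L, 110000L))
})

test_that("the twelve chromosome-1 oleic/linoleic markers give four regions", {
    mk <- table3Markers()
    expect_identical(nrow(mk), 12L)
    iv <- buildIntervals(mk, flank = 50000)
    expect_true(all(GenomicRanges::width(iv) == 100001L |
                        GenomicRanges::start(iv) == 1L))
    reg <- mergeIntervals(iv, gapTol = 1000)
    expect_identical(length(reg), 4L)
    # the near-touching pair (804 bp gap) merges; a 10 kb gap does not
    expect_true(all(c("SNP_591", "SNP_653") %in%
                        unlist(reg$member_marker_ids[1L])))
    far <- GenomicRanges::GRanges(
        "chr1", IRanges::IRanges(c(1L, 20001L), c(10000L, 30000L)))
    far$marker_id <- c("x", "y")
    expect_identical(length(mergeIntervals(far, gapTol = 1000)), 2L)
})

test_that("merging matches a union-find oracle on random instances", {
    set.seed(401)
    for (k in 1:60) {
        n <- sample(2:40, 1L)
        chrom <- sample(paste0("chr", 1:3), n, replace = TRUE)
        start <- sample.int(100000L, n, replace = TRUE)
        width <- sample.int(20000L, n, replace = TRUE)
        gapTol <- sample(c(0L, 500L, 1000L, 5000L), 1L)
        gr <- GenomicRanges::GRanges(
            chrom, IRanges::IRanges(start, start + width))
        gr$marker_id <- paste0("m", seq_len(n))
        got <- mergeIntervals(gr, gapTol)
        want <- mergeOracle(chrom, start, start + width, gapTol)
        expect_identical(length(got), nrow(want))
        expect_identical(GenomicRanges::start(got), want$start)
        expect_identical(GenomicRanges::end(got), want$end)
        expect_identical(unname(lengths(got$member_marker_ids)),
                         want$n)
    }
})

test_that("merging is idempotent, order-invariant, and marker-complete", {
    set.seed(402)
    n <- 30L
    gr <- GenomicRanges::GRanges(
        sample(c("chr1", "chr2"), n, TRUE),
        IRanges::IRanges(sample.int(50000L, n),
                         width = sample.int(8000L, n)))
    gr$marker_id <- paste0("m", seq_len(n))
    a <- mergeIntervals(gr, 1000)
    b <- mergeIntervals(gr[sample(n)], 1000)
    expect_identical(GenomicRanges::start(a), GenomicRanges::start(b))
    expect_identical(sort(unlist(a$member_marker_ids)),
                     sort(unlist(b$member_marker_ids)))
    # every marker in exactly one region
    expect_identical(sort(unlist(a$member_marker_ids)),
                     sort(gr$marker_id))
    # widths can only shrink through merging
    expect_lte(sum(GenomicRanges::width(a)),
               sum(GenomicRanges::width(gr)))
})

test_that("genes attach by 1 bp span overlap, once per region", {
    ref <- fixRef()
    anno <- ref$annotation
    g1 <- genes(anno)[1L]
    reg <- GenomicRanges::GRanges(
        GenomicRanges::seqnames(g1),
        IRanges::IRanges(GenomicRanges::end(g1),
                         GenomicRanges::end(g1) + 500L))
    expect_identical(genesInRegion(reg, anno), names(g1))
    # intergenic region -> empty (generator leaves >= 1.5 kb gaps)
    gs <- genes(anno)
    gs1 <- gs[as.character(GenomicRanges::seqnames(gs)) == "chr1"]
    gs1 <- gs1[order(GenomicRanges::start(gs1))]
    mid_lo <- GenomicRanges::end(gs1)[1L] + 400L
    mid <- GenomicRanges::GRanges(
        "chr1", IRanges::IRanges(mid_lo, mid_lo + 100L))
    expect_length(genesInRegion(mid, anno), 0L)
    expect_error(
        genesInRegion(GenomicRanges::GRanges(
            "chrX", IRanges::IRanges(1, 10)), anno),
        "unknown chromosome")
    # brute-force interval scan agreement across many random regions
    set.seed(403)
    gspan <- genes(anno)
    for (k in 1:25) {
        ch <- sample(c("chr1", "chr2"), 1L)
        a <- sample.int(35000L, 1L); b <- min(40000L, a + 3000L)
        reg <- GenomicRanges::GRanges(ch, IRanges::IRanges(a, b))
        want <- names(gspan)[as.character(
            GenomicRanges::seqnames(gspan)) == ch &
            GenomicRanges::start(gspan) <= b &
            GenomicRanges::end(gspan) >= a]
        expect_setequal(genesInRegion(reg, anno), want)
    }
})

test_that("gene-density arithmetic reproduces the genome-wide figures", {
    bp_per_gene <- 650e6 / 138000
    expect_equal(round(bp_per_gene), 4710)
    expect_equal(round(bp_per_gene / 100) * 100, 4700)
    g100 <- expectedGeneCount(1e5, 650e6, 138000)
    expect_gte(g100, 20); expect_lte(g100, 25)
    expect_equal(expectedGeneCount(0, 650e6, 138000), 0)
    expect_error(expectedGeneCount(1e5, 650e6, 0), "division")
})

test_that("BED output is 0-based half-open", {
    gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(100L, 200L))
    gr$member_marker_ids <- IRanges::CharacterList(list(c("a", "b")))
    f <- withr::local_tempfile(fileext = ".bed")
    writeRegionsBed(gr, f)
    bed <- read.delim(f, header = FALSE)
    expect_identical(bed$V2, 99L)
    expect_identical(bed$V3, 200L)
    expect_identical(bed$V4, "a;b")
})
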