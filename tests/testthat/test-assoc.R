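# PCA covariates, the single-marker OLS test, and the iterative
# remove-and-rescan region procedure.

test_that("PCA covariates behave like a decomposition should", {
    ms <- fixPanel()
    pc <- pcaCovariates(ms, 4L)
    expect_identical(dim(pc), c(200L, 4L))
    ev <- attr(pc, "explained")
    expect_true(all(diff(ev) <= 1e-12))  # decreasing
    expect_lte(sum(ev), 1)
    # duplicated accessions get identical scores
    d <- dosages(ms)[, c(1:20, 1L)]
    colnames(d) <- c(accessionIds(ms)[1:20], "dup")
    rr <- SummarizedExperiment::rowRanges(ms)
    ms2 <- MarkerSet(d, as.character(GenomicRanges::seqnames(rr)),
                     GenomicRanges::start(rr),
                     unname(refAllele(ms)), unname(altAllele(ms)),
                     id = markerIds(ms))
    pc2 <- pcaCovariates(ms2, 3L)
    expect_equal(unname(pc2[1L, ]), unname(pc2[21L, ]),
                 tolerance = 1e-8)
})

test_that("PCA separates two planted subpopulations on component 1", {
    set.seed(42)
    n <- 60L; m <- 120L
    subpop <- rep(c(0L, 1L), each = n / 2L)
    p0 <- runif(m, 0.05, 0.4); p1 <- pmin(0.95, p0 + 0.4)
    d <- vapply(seq_len(n), function(a)
        rbinom(m, 2L, ifelse(subpop[a] == 1L, p1, p0)),
        integer(m))
    ms <- MarkerSet(d, rep("chr1", m), seq_len(m) * 100L,
                    rep("A", m), rep("T", m))
    pc <- pcaCovariates(ms, 2L)
    s1 <- pc[subpop == 0L, 1L]; s2 <- pc[subpop == 1L, 1L]
    expect_true(max(s1) < min(s2) || max(s2) < min(s1))
})

test_that("single-marker OLS recovers planted effects", {
    # perfect fit: trait equals dosage
    d <- rep(0:2, length.out = 30L)
    r <- suppressWarnings(singleMarkerTest(d, d))  # exact fit warns
    expect_lt(r$p_value, 1e-20)
    expect_gt(r$pve, 99.9)
    expect_equal(r$effect, 1, tolerance = 1e-8)
    # planted effect +1 per allele, n = 200, noise sd 1
    set.seed(202)
    d2 <- rbinom(200L, 2L, 0.3)
    tr <- d2 * 1.0 + rnorm(200L, 0, 1)
    r2 <- singleMarkerTest(d2, tr)
    expect_lt(abs(r2$effect - 1), 0.25)
    # monomorphic markers are skipped with a flag, not an error
    r3 <- singleMarkerTest(rep(1L, 20L), rnorm(20L))
    expect_identical(r3$note, "monomorphic")
    expect_true(is.na(r3$p_value))
})

test_that("type-I error is calibrated near 5% under the null", {
    set.seed(203)
    n <- 120L
    tr <- rnorm(n)
    p <- replicate(1000L, {
        d <- rbinom(n, 2L, runif(1L, 0.1, 0.5))
        singleMarkerTest(d, tr)$p_value
    })
    expect_gt(mean(p < 0.05, na.rm = TRUE), 0.03)
    expect_lt(mean(p < 0.05, na.rm = TRUE), 0.07)
})

test_that("effect sign flips under ref/alt swap", {
    set.seed(204)
    d <- rbinom(100L, 2L, 0.4)
    tr <- d * 0.7 + rnorm(100L, 0, 0.5)
    a <- singleMarkerTest(d, tr)
    b <- singleMarkerTest(2L - d, tr)
    expect_equal(a$effect, -b$effect, tolerance = 1e-10)
    expect_equal(a$p_value, b$p_value, tolerance = 1e-10)
})

test_that("iterative scan recovers planted markers and stops on null", {
    ms <- fixIndepPanel()
    reg <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(1L, 200000L))
    rr <- SummarizedExperiment::rowRanges(ms)
    on_chr1 <- which(as.character(GenomicRanges::seqnames(rr)) ==
                         "chr1")
    causal <- markerIds(ms)[on_chr1[c(5L, 25L, 45L)]]
    eff <- stats::setNames(c(1.2, 1.0, -1.1), causal)
    ph <- makePhenotypes(ms, eff, heritability = 0.8, seed = 31L)
    trait <- stats::setNames(ph[[1L]], rownames(ph))
    res <- iterativeRegionScan(ms, trait, reg, maxIter = 6L)
    expect_setequal(res$marker_id, causal)
    expect_lte(nrow(res), 3L)
    expect_false(attr(res, "truncated"))
    # single planted marker: exactly one result
    eff1 <- eff[1L]
    ph1 <- makePhenotypes(ms, eff1, heritability = 0.8, seed = 32L)
    res1 <- iterativeRegionScan(
        ms, stats::setNames(ph1[[1L]], rownames(ph1)), reg)
    expect_identical(res1$marker_id, names(eff1))
    # null trait: empty result under Bonferroni
    ph0 <- makePhenotypes(ms, heritability = 0.8, seed = 33L)
    res0 <- iterativeRegionScan(
        ms, stats::setNames(ph0[[1L]], rownames(ph0)), reg)
    expect_identical(nrow(res0), 0L)
})

test_that("the scan is its own oracle under marker removal", {
    ms <- fixIndepPanel()
    reg <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(1L, 200000L))
    rr <- SummarizedExperiment::rowRanges(ms)
    on_chr1 <- which(as.character(GenomicRanges::seqnames(rr)) ==
                         "chr1")
    causal <- markerIds(ms)[on_chr1[c(10L, 30L)]]
    ph <- makePhenotypes(ms, stats::setNames(c(1.3, 1.0), causal),
                         heritability = 0.85, seed = 34L)
    trait <- stats::setNames(ph[[1L]], rownames(ph))
    res <- iterativeRegionScan(ms, trait, reg)
    expect_gte(nrow(res), 2L)
    # markers are unique and in-region
    expect_false(anyDuplicated(res$marker_id) > 0L)
    hit_rr <- rr[res$marker_id]
    expect_true(all(IRanges::overlapsAny(hit_rr, reg)))
    # removing the first find and rescanning reproduces the remainder
    ms2 <- ms[setdiff(markerIds(ms), res$marker_id[1L]), ]
    res2 <- iterativeRegionScan(ms2, trait, reg)
    expect_identical(res2$marker_id, res$marker_id[-1L])
})
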