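# The generator itself: determinism, construction invariants, and the
# fidelity of planted mutation classes.

test_that("generation is byte-identical for identical seeds", {
    d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
    r1 <- makeReference(nChrom = 1L, chromLen = 20000L, nGenes = 4L,
                        seed = 99L)
    r2 <- makeReference(nChrom = 1L, chromLen = 20000L, nGenes = 4L,
                        seed = 99L)
    writeReference(r1, d1); writeReference(r2, d2)
    expect_identical(readLines(file.path(d1, "ref.fa")),
                     readLines(file.path(d2, "ref.fa")))
    expect_identical(readLines(file.path(d1, "genes.gff3")),
                     readLines(file.path(d2, "genes.gff3")))
    p1 <- makePopulation(r1, 30L, 40L, 5000L, seed = 98L)
    p2 <- makePopulation(r2, 30L, 40L, 5000L, seed = 98L)
    expect_identical(dosages(p1), dosages(p2))
    expect_error(makeReference(nChrom = 1L, chromLen = 5000L,
                               nGenes = 10L, seed = 1L), "capacity")
})

test_that("every generated CDS is a clean open reading frame", {
    ref <- fixRef()
    for (g in ref$gene_ids) {
        m <- extractMrna(ref$annotation, g, ref$genome)
        cds <- paste(strsplit(as.character(m$seq), "")[[1L]][
            m$label == "cds"], collapse = "")
        aa <- translateOracle(cds)
        expect_identical(substr(aa, 1L, 1L), "M")
        expect_identical(substr(aa, nchar(aa), nchar(aa)), "*")
        expect_false(grepl("\\*", substr(aa, 1L, nchar(aa) - 1L)))
    }
    # introns are canonical GT..AG
    anno <- ref$annotation
    for (g in ref$gene_ids) {
        gr <- genes(anno)[g]
        introns <- GenomicRanges::setdiff(gr, exonsBy(anno)[[g]],
                                          ignore.strand = TRUE)
        st <- as.character(GenomicRanges::strand(gr))
        ch <- as.character(GenomicRanges::seqnames(gr))
        for (i in seq_along(introns)) {
            s <- Biostrings::subseq(ref$genome[[ch]],
                                    GenomicRanges::start(introns)[i],
                                    GenomicRanges::end(introns)[i])
            if (st == "-") s <- Biostrings::reverseComplement(s)
            s <- as.character(s)
            expect_identical(substr(s, 1L, 2L), "GT")
            expect_identical(substr(s, nchar(s) - 1L, nchar(s)), "AG")
        }
    }
})

test_that("planted edits have exactly the promised footprint", {
    ref <- fixRef()
    # a synonymous substitution changes one base and no amino acid
    plan <- data.frame(member = "m1",
                       gene_id = ref$gene_ids[1:4],
                       class = c("syn_sub", "nonsyn_sub", "utr_sub",
                                 "none"))
    pg <- makePangenome(ref, plan, seed = 60L)
    g <- pg$members$m1
    diffs <- sum(vapply(names(g), function(ch) {
        a <- strsplit(as.character(ref$genome[[ch]]), "")[[1L]]
        b <- strsplit(as.character(g[[ch]]), "")[[1L]]
        sum(a != b)
    }, numeric(1L)))
    expect_identical(diffs, 3)  # one base per planted substitution
    for (gid in plan$gene_id[1:2]) {
        m0 <- extractMrna(ref$annotation, gid, ref$genome)
        cds0 <- paste(strsplit(as.character(m0$seq), "")[[1L]][
            m0$label == "cds"], collapse = "")
        m1 <- extractMrna(ref$annotation, gid, g)
        cds1 <- paste(strsplit(as.character(m1$seq), "")[[1L]][
            m1$label == "cds"], collapse = "")
        expect_false(identical(cds0, cds1))
        same_aa <- identical(translateOracle(cds0),
                             translateOracle(cds1))
        expect_identical(same_aa,
                         plan$class[plan$gene_id == gid] == "syn_sub")
    }
})

test_that("marker panels honor their planted construction", {
    ref <- fixPopRef()
    # no missingness requested -> none present
    ms0 <- makePopulation(ref, 30L, 50L, 25000L, missingRate = 0,
                          seed = 61L)
    expect_false(anyNA(dosages(ms0)))
    # perfect within-block LD at zero flip noise
    ms1 <- makePopulation(ref, 80L, 120L, 50000L, flipNoise = 0,
                          missingRate = 0, seed = 62L)
    truth <- attr(ms1, "truth")
    blocks <- split(truth$id, truth$block)
    blocks <- blocks[lengths(blocks) >= 2L]
    d <- dosages(ms1)
    for (b in blocks[1:5]) {
        r2 <- pairwiseR2(d[b[1L], ], d[b[2L], ])
        expect_equal(r2, 1)
    }
    # latent frequencies respect the requested range
    expect_true(all(truth$block_freq >= 0.1 & truth$block_freq <= 0.4))
    # realised MAFs stay near the latent range (binomial tolerance)
    maf <- minorAlleleFrequency(ms1)
    expect_true(mean(maf > 0.05) > 0.95)
})

test_that("phenotypes scale noise to the requested heritability", {
    ms <- fixIndepPanel()
    eff <- stats::setNames(1, markerIds(ms)[3L])
    # heritability 1: trait is a deterministic function of dosage
    ph <- makePhenotypes(ms, eff, heritability = 1, seed = 63L)
    d <- dosages(ms)[names(eff), ]
    expect_equal(unname(cor(ph[[1L]], d, method = "spearman")), 1)
    # h2 = 0.8 over replicates: genetic variance fraction near 0.8
    ph2 <- makePhenotypes(ms, eff, heritability = 0.8, nTraits = 30L,
                          seed = 64L)
    g <- as.numeric(d)
    vr <- vapply(ph2, function(y) var(g) / var(y), numeric(1L))
    expect_equal(mean(vr), 0.8, tolerance = 0.05)
    expect_error(makePhenotypes(ms, stats::setNames(
        1, markerIds(ms)[1L]), heritability = 0.5, seed = 1L),
        NA)
})

test_that("full fixture simulation writes a coherent bundle", {
    d <- withr::local_tempdir()
    fx <- simulateFixtures(d, seed = 70L)
    expect_true(all(file.exists(file.path(
        d, c("ref.fa", "genes.gff3", "panel.vcf", "pheno.tsv",
             "truth.json")))))
    expect_length(list.files(file.path(d, "members")), 5L)
    ms <- readMarkerVcf(file.path(d, "panel.vcf"))
    expect_identical(nrow(ms), 150L)
    ph <- readPhenotypes(file.path(d, "pheno.tsv"))
    expect_identical(rownames(ph), accessionIds(ms))
    tr <- jsonlite::read_json(file.path(d, "truth.json"),
                              simplifyVector = TRUE)
    expect_setequal(unique(tr$truth$expected_pairwise),
                    setdiff(pairwiseClasses(), character(0L)))
})
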