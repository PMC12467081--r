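# Shared fixtures, built once per test run (all generated in code; no
# binary files). Builders are memoised so expensive objects are reused
# across test files.

.fix_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
    if (!exists(name, envir = .fix_env))
        assign(name, builder(), envir = .fix_env)
    get(name, envir = .fix_env)
}

# small reference: 2 chromosomes, 10 genes
fixRef <- function() fixture("ref", function()
    makeReference(nChrom = 2L, chromLen = 40000L, nGenes = 10L,
                  seed = 7L))

# pangenome over the small reference with all nine classes planted
fixPangenome <- function() fixture("pangenome", function() {
    ref <- fixRef()
    plan <- planPangenome(ref, nMembers = 5L, seed = 8L)
    makePangenome(ref, plan, seed = 9L)
})

# larger reference for population work (LD, scans)
fixPopRef <- function() fixture("popref", function()
    makeReference(nChrom = 2L, chromLen = 200000L, nGenes = 20L,
                  seed = 11L))

# LD-block panel: 25 kb blocks, 200 accessions
fixPanel <- function() fixture("panel", function()
    makePopulation(fixPopRef(), nAccessions = 200L, nMarkers = 400L,
                   blockLen = 25000L, missingRate = 0.02, seed = 12L))

# panel of independent markers (every marker its own haplotype block)
fixIndepPanel <- function() fixture("indep", function()
    makePopulation(fixPopRef(), nAccessions = 200L, nMarkers = 150L,
                   blockLen = 1L, flipNoise = 0, missingRate = 0,
                   seed = 13L))

table3Markers <- function()
    readMarkerTable(system.file("extdata",
                                "camelina_chr1_oleic_markers.tsv",
                                package = "panQTL"))
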