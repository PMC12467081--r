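## Orchestration: filter -> ld -> scan -> regions -> classify as one
## reproducible run with validated configuration, per-stage counts, and a
## machine-readable JSON manifest.

.defaultConfig <- function() {
    list(max_missing = 0.2, biallelic_only = TRUE,
         ld_max_dist = 200000, ld_bin_width = 1000,
         pca_count = 4, alpha = 0.05, max_iter = 10,
         flank = 50000, gap_tol = 1000,
         min_count = 7, carrier_min_dosage = 1,
         classify_flank = 300, seed_k = 15,
         min_identity = 0.8, min_coverage = 0.5,
         stages = c("filter", "ld", "scan", "regions", "classify"))
}

.validateConfig <- function(config) {
    def <- .defaultConfig()
    unknown_ok <- c("vcf", "ref", "gff", "members", "pheno", "trait",
                    "region", "out_dir", "markers")
    config <- utils::modifyList(def, config)
    chk <- function(cond, what) if (!cond)
        stop("invalid config: ", what)
    chk(config$max_missing >= 0 && config$max_missing <= 1,
        "max_missing in [0,1]")
    chk(config$ld_bin_width > 0 &&
            config$ld_max_dist >= config$ld_bin_width,
        "ld_max_dist >= ld_bin_width > 0")
    chk(config$pca_count >= 0, "pca_count >= 0")
    chk(config$alpha > 0 && config$alpha < 1, "alpha in (0,1)")
    chk(config$flank > 0, "flank > 0")
    chk(config$gap_tol >= 0, "gap_tol >= 0")
    chk(config$min_identity > 0 && config$min_identity <= 1,
        "min_identity in (0,1]")
    chk(config$min_coverage > 0 && config$min_coverage <= 1,
        "min_coverage in (0,1]")
    chk(config$seed_k >= 4, "seed_k >= 4")
    chk(all(config$stages %in% def$stages), "unknown stage name")
    config
}

.parseRegion <- function(s) {
    m <- regmatches(s, regexec("^([^:]+):([0-9]+)-([0-9]+)$", s))[[1L]]
    if (length(m) != 4L)
        stop("region must look like chr1:1000-2000, got: ", s)
    GenomicRanges::GRanges(m[2L],
                           IRanges::IRanges(as.integer(m[3L]),
                                            as.integer(m[4L])))
}

#' Run the full marker-to-candidate-gene pipeline
#'
#' Executes the enabled stages in order --- filter (VCF in, biallelic +
#' missingness filters), ld (decay curve and half-width), scan
#' (PCA covariates + iterative region scan), regions (flanked interval
#' merging, BED out), classify (pangenome alignment classification) ---
#' writing intermediate files under \code{out_dir} and a JSON manifest
#' recording parameters, input checksums, and per-stage row counts. Any
#' stage can be skipped via \code{config$stages}; later stages then fall
#' back to earlier outputs present in the config.
#'
#' @param config named list (or path to a YAML file): input paths
#'   (\code{vcf}, \code{ref}, \code{gff}, \code{members} (vector of
#'   FASTA paths), \code{pheno}, \code{trait}, \code{region} as
#'   \code{"chr:start-end"}, \code{markers} marker-table TSV),
#'   \code{out_dir}, and parameters (see Details in the package
#'   vignette); missing parameters take documented defaults.
#' @return the manifest, invisibly (also written to
#'   \code{out_dir/manifest.json}).
#' @export
runPipeline <- function(config) {
    if (is.character(config) && length(config) == 1L)
        config <- yaml::read_yaml(config)
    config <- .validateConfig(config)
    if (is.null(config$out_dir)) stop("config$out_dir is required")
    out <- config$out_dir
    if (!dir.exists(out)) dir.create(out, recursive = TRUE)
    inputs <- unlist(config[c("vcf", "ref", "gff", "pheno", "markers")])
    inputs <- c(inputs, unlist(config$members))
    inputs <- inputs[!is.na(inputs) & nzchar(inputs)]
    missing_in <- inputs[!file.exists(inputs)]
    if (length(missing_in))
        stop("missing input file(s): ",
             paste(missing_in, collapse = ", "))
    manifest <- list(
        parameters = config[setdiff(names(config),
                                    c("members", "stages"))],
        stages_requested = config$stages,
        input_md5 = as.list(tools::md5sum(inputs)),
        stages = list())
    note <- function(stage, status, counts = list())
        manifest$stages[[stage]] <<- c(list(status = status), counts)
    ms <- NULL; scan_res <- NULL; regions <- NULL

    if ("filter" %in% config$stages) {
        ms <- readMarkerVcf(config$vcf)
        n0 <- nrow(ms)
        if (isTRUE(config$biallelic_only)) ms <- filterBiallelic(ms)
        ms <- filterMissingness(ms, config$max_missing)
        writeMarkerVcf(ms, file.path(out, "filtered.vcf"))
        note("filter", "complete",
             list(markers_in = n0, markers_out = nrow(ms)))
    } else note("filter", "skipped")

    if ("ld" %in% config$stages) {
        if (is.null(ms)) ms <- readMarkerVcf(config$vcf)
        curve <- decayCurve(ms, config$ld_max_dist, config$ld_bin_width)
        utils::write.table(as.data.frame(curve),
                           file.path(out, "ld_curve.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        hw <- linkedRegionHalfwidth(curve)
        note("ld", "complete",
             list(n_pairs = sum(curve@pairCount),
                  halfwidth_bp = as.numeric(hw),
                  crossed = attr(hw, "crossed")))
    } else note("ld", "skipped")

    if ("scan" %in% config$stages) {
        if (is.null(ms)) ms <- readMarkerVcf(config$vcf)
        ph <- readPhenotypes(config$pheno)
        if (!config$trait %in% colnames(ph))
            stop("trait '", config$trait, "' not in phenotype table")
        trait <- stats::setNames(ph[[config$trait]], rownames(ph))
        cov <- if (config$pca_count > 0)
            pcaCovariates(ms, config$pca_count) else NULL
        scan_res <- iterativeRegionScan(
            ms, trait, .parseRegion(config$region), cov,
            alpha = config$alpha, maxIter = config$max_iter)
        utils::write.table(scan_res, file.path(out, "scan.tsv"),
                           sep = "\t", quote = FALSE,
                           row.names = FALSE)
        note("scan", "complete",
             list(markers_found = nrow(scan_res),
                  truncated = attr(scan_res, "truncated")))
    } else note("scan", "skipped")

    if ("regions" %in% config$stages) {
        mk <- if (!is.null(config$markers))
            readMarkerTable(config$markers)
        else if (!is.null(scan_res) && nrow(scan_res)) {
            rr <- SummarizedExperiment::rowRanges(ms)
            hit <- rr[scan_res$marker_id]
            data.frame(id = scan_res$marker_id,
                       chrom = as.character(
                           GenomeInfoDb::seqnames(hit)),
                       pos = BiocGenerics::start(hit))
        } else stop("regions stage needs config$markers or scan hits")
        regions <- mergeIntervals(buildIntervals(mk, config$flank),
                                  config$gap_tol)
        writeRegionsBed(regions, file.path(out, "regions.bed"))
        note("regions", "complete",
             list(markers_in = nrow(mk), regions_out = length(regions)))
    } else note("regions", "skipped")

    if ("classify" %in% config$stages) {
        if (is.null(regions))
            stop("classify stage needs the regions stage")
        genome <- Biostrings::readDNAStringSet(config$ref)
        names(genome) <- sub("\\s.*", "", names(genome))
        anno <- readAnnotation(config$gff)
        members <- lapply(config$members, function(p) {
            g <- Biostrings::readDNAStringSet(p)
            names(g) <- sub("\\s.*", "", names(g))
            g
        })
        names(members) <- sub("\\.(fa|fasta)$", "",
                              basename(unlist(config$members)))
        res <- classifyRegions(regions, genome, anno, members,
                               flank = config$classify_flank,
                               outDir = file.path(out, "alignments"),
                               seedK = config$seed_k,
                               minIdentity = config$min_identity,
                               minCoverage = config$min_coverage)
        utils::write.table(res$summary,
                           file.path(out, "classify_summary.tsv"),
                           sep = "\t", quote = FALSE,
                           row.names = FALSE)
        utils::write.table(res$genes,
                           file.path(out, "classify_genes.tsv"),
                           sep = "\t", quote = FALSE,
                           row.names = FALSE)
        note("classify", "complete",
             list(genes = nrow(res$genes),
                  failures = length(res$failures)))
    } else note("classify", "skipped")

    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    invisible(manifest)
}
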