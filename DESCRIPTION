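Package: panQTL
Title: Marker-to-Candidate-Gene Analysis with Pangenome Alignment
    Classification for Oilseed QTLs
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for interpreting quantitative trait locus (QTL) hits from
    genome-wide association scans in an oilseed diversity panel. Provides
    marker filtering from VCF (biallelic sites, missingness, minor allele
    frequency), genome-wide linkage-disequilibrium decay estimation used to
    size candidate intervals, an iterative conditional region scan that
    removes and re-tests significant markers, haplotype-group assignment with
    additive total-effect scoring and one-way ANOVA comparison, construction
    and merging of flanked marker intervals with gene attachment from GFF3
    annotation, and a pangenome alignment-classification engine that locates
    each candidate gene in every pangenome member by seed-and-extend homology
    search, aligns it to the reference with an affine-gap global aligner, and
    sorts genes into protein-altering, silent-CDS, non-coding-only, and
    no-match/no-difference categories. A synthetic-data generator produces
    reference genomes, annotations, pangenome members with planted mutation
    classes, marker panels with linkage-disequilibrium block structure, and
    phenotypes with planted QTL effects, providing ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    Biostrings,
    VariantAnnotation,
    rtracklayer,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    withr
biocViews: Genetics, SNP, GenomeWideAssociationStudies, Alignment,
    SequenceMatching, VariantAnnotation
Config/testthat/edition: 3
RoxygenNote: 7.3.3
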