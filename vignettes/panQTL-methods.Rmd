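---
title: "From association markers to classified candidate genes: methods and design"
author: "panQTL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From association markers to classified candidate genes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# Scope

`panQTL` takes the output of a genome-wide association scan in a crop
diversity panel — a set of trait-associated markers — and carries it to a
prioritised list of candidate genes. The package covers five connected
steps: marker-set quality filtering from VCF; genome-wide
linkage-disequilibrium (LD) decay estimation, which sets the physical
search window around each marker; an iterative remove-and-rescan
association procedure that resolves multiple linked signals inside one
region; haplotype-group scoring with additive total effects; and a
pangenome alignment classifier that sorts every gene in every candidate
region into protein-altering, silent-CDS, non-coding-only, or
no-match/no-difference categories across the members of a pangenome. A
synthetic-data generator with planted ground truth underpins the test
suite end to end.

The motivating application is seed fatty-acid composition in the
hexaploid oilseed *Camelina sativa*, where oleic-acid (18:1) QTLs on
chromosome 1 recur across growth environments and a 12-member pangenome
is available for cross-accession validation. Nothing in the code is
specific to that system: inputs are ordinary VCF, FASTA, GFF3 and
delimited phenotype tables.

# Marker filtering

Genotypes are collapsed to dosages (count of non-reference alleles,
0/1/2/NA). Phase is discarded — none of the downstream methods use it —
and half-missing genotypes (`0/.`) are treated as fully missing rather
than given fractional dosages. Multi-allelic records are read and flagged
rather than dropped at parse time, so the biallelic filter is an explicit,
testable step. The missingness filter removes markers whose missing
fraction is *at least* the threshold (default 0.2): retention is
strict-less-than, so a marker with exactly 20% missing data is removed.
Minor allele frequency is the folded alternate-allele frequency over
non-missing calls, in [0, 0.5], invariant under ref/alt swap.

Read-level filters (depth, mapping and base quality) belong to upstream
variant calling and are out of scope; the package starts from a called
VCF.

# LD decay and interval sizing

Pairwise LD is the squared Pearson correlation of genotype dosages over
pairwise-complete accessions — the composite, Plink-style estimator.
Phase-aware EM estimation was rejected as unnecessary: the decay curve is
used only to choose a physical window size. Pairs where either marker is
constant after pairwise deletion return r² = 0 rather than NA, so
monomorphic markers cannot poison a distance bin; inter-chromosome pairs
are excluded (distance undefined); empty bins are NA, never zero.

The *linked-region half-width* is the left edge of the first non-empty
bin whose mean r² drops below a threshold (0.1 by convention — the same
"LD below 0.1" rule commonly used to delimit linked regions). If the
curve never crosses, the maximum distance is returned with a
`crossed = FALSE` attribute rather than a fabricated crossing.

Region construction interprets "a 50 kb interval for each marker" as a
*one-sided* flank (total span ~100 kb). This matches the package's own
gene-density arithmetic: at one gene per ~4.7 kb (650 Mbp assembly,
138 k gene models), a 100 kb span holds 20–25 genes, which is the
mid-range candidate load the method targets. Intervals whose gap is at
most `gapTol` (default 1 kb) merge transitively into composite regions,
preventing repeated analysis of genes shared by overlapping intervals.
The 1 kb tolerance deliberately absorbs interval pairs that miss touching
by a few hundred base pairs — markers that close are linked at any
realistic decay rate — and is exposed in configuration. Coordinates are
1-based inclusive internally (VCF/GFF convention); BED output converts to
0-based half-open.

# The iterative region scan

Multi-locus GWAS models report a single representative marker per linked
group. The procedure implemented here mirrors how such scans are used in
practice to enumerate *all* signals in a region: test every remaining
marker, and if the most significant marker inside the region passes a
Bonferroni threshold (α divided by the number of markers actually
tested, α = 0.05 by default — a deliberate, conservative default since
no genome-wide threshold is canonical), record it, remove it from the
marker set, and rescan, until nothing in the region is significant or an
iteration cap is hit.

The per-marker test is ordinary least squares of the trait on dosage
plus covariates plus an intercept, over pairwise-complete observations:
p from the two-sided t-test of the dosage coefficient, effect = the
dosage coefficient (trait units per non-reference allele copy), and PVE
defined as 100 × R² of the dosage-only fit to the covariate-residualised
trait. This is an explicit, documented stand-in for heavier multi-locus
machinery (BLINK/FarmCPU-class models): the contract of the iteration is
independent of the test's internals, and the test function is pluggable.
Two consequences are worth stating plainly. First, with a
single-marker OLS test, removing a marker does not change the statistics
of the others, so the literal remove-and-rescan reduces to greedy
thresholded selection in p-value order; `condition = TRUE` turns on true
conditional scanning (discovered markers become covariates), which is
the behaviour that makes removal informative under linkage. Second, no
kinship correction is applied beyond the PCA covariates — a documented
limitation, acceptable for the synthetic panels the package validates
against, visible as inflation risk on strongly structured real panels.

Population structure is summarised by principal components of the
mean-imputed, centered dosage matrix; four components is the default
count, the value that in the motivating study balanced false-positive
removal against retained signal.

Whether the original iterative procedure re-ran genome-wide or
region-restricted scans is ambiguous in its description; here all
markers are tested (so the Bonferroni denominator is honest) while the
stopping rule and reporting are region-restricted. This interpretation
is surfaced in the function contract rather than hidden.

# Haplotype groups and additive effects

An accession *carries* a marker when its dosage is ≥ 1 — heterozygous
carriage suffices, since the source material does not resolve het/hom
for group membership; the threshold is exposed as
`carrierMinDosage`. Accessions carrying at least `minCount` (default 7)
of a defined marker set form haplotype 2. Missing dosages count as not
carried — conservative, never promoting an accession on imputed
evidence. Group trait distributions are compared by classic one-way
fixed-effects ANOVA, with the degenerate all-identical case returned as
F = 0, p = 1 instead of NaN.

The total additive effect of a marker set is Σ effect × dosage — the
expected trait shift under per-allele additivity. Missing dosages
contribute zero and clear a completeness flag rather than erroring.

# The pangenome classifier

For every gene in every candidate region, the classifier runs:
extract → search → align → classify → categorize.

**Extraction.** The default alignment unit is the *unspliced* gene body
plus a non-coding flank (default 300 bp), with every position labeled
`cds`, `utr`, `intron`, or `flank`. Spliced-mRNA extraction is also
provided (and is how reference transcript FASTAs are built), but
aligning a spliced mRNA against a member's genomic locus renders every
intron as a large insertion, which would mark all multi-exon genes as
having non-coding differences and empty the intron/non-coding category
of meaning. Genomic mode labels introns directly and keeps the
category informative; it is therefore the classify default, with mRNA
mode available as a switch. Minus-strand genes are reverse-complemented
so all comparisons read 5′→3′ in transcript orientation.

**Search.** Homology search is internal seed-and-extend rather than a
wrapped external aligner: exact, non-overlapping k-mer seeds (k = 15)
of the query are located on both strands of each member sequence via
2-bit k-mer hashing; seeds within a 100 bp diagonal band are chained;
each candidate window is extended and scored by affine-gap local
alignment. The best hit must pass minimum identity (0.8, fraction of
identical columns) and minimum query coverage (0.5); otherwise the gene
has *no match* in that member — a value, not an error. Score ties break
to the lexicographically lowest (sequence, start) so output is
deterministic. The scoring parameters (+2 match, −3 mismatch, −5 gap
open, −2 gap extend) sit near blastn defaults and are configurable; no
published cut-offs existed to copy, so these are package decisions.

**Alignment.** Reference and member sequence are aligned by an
affine-gap global Needleman–Wunsch (same scoring). The gap-cost
convention is: a gap of length L costs open + L × extend, i.e. the
first gap column pays both open and extend. Feature labels are
projected onto alignment columns; a column where the reference row is a
gap (an insertion in the member) inherits the label of the preceding
reference position, so insertions are attributed to the enclosing
feature interval, with the 5′-most column falling back to the first
label. The aligner is implemented in C++ (integer scores, rolling rows,
packed traceback bytes) because the validation suite aligns hundreds of
multi-kilobase pairs; its scores are checked against an independent
library implementation of the same model in the tests.

**Classification cascade.** Per member, in order: (1) any CDS-column
change that alters the protein — a non-synonymous substitution, *any*
CDS indel (a frameshift if not a multiple of 3, an in-frame residue
insertion/deletion otherwise), or a gained/lost stop or start — gives
`PROTEIN_DIFF`; (2) otherwise any CDS nucleotide difference gives
`SILENT_CDS`; (3) otherwise any difference in non-coding columns gives
`NONCODING_ONLY`; (4) otherwise `NO_DIFF`; with `NO_MATCH` assigned
upstream by the search. Member CDS sequences are reconstructed from the
cds-labeled columns (spliced in silico through the label map) and
translated with initiator-codon special-casing disabled, so a mutated
ATG reads as its literal amino acid and start loss surfaces as a
protein difference. Ambiguous (non-ACGT) bases score as mismatches in
alignment but never trigger a difference classification by themselves.

**Gene categories.** With P = number of members showing protein
differences: P ≥ 4 → `PROTEIN_DIFF_4PLUS`; 1 ≤ P ≤ 3 →
`PROTEIN_DIFF_1TO3`; else any silent CDS difference → `SILENT_CDS`;
else any non-coding-only difference → `NONCODING_ONLY`; else
`NO_MATCH_OR_NO_DIFF`. The categories are conditionally exclusive,
ordered from more to fewer differences, and always partition the gene
set — a row-sum identity asserted on every summary the package emits.
Classification is defined per reference–member pair, so alignment is
pairwise rather than a joint multiple alignment of all members; a joint
alignment adds nothing to a per-member verdict and is deliberately
omitted.

# The synthetic-data generator

The generator is first-class, tested code, not a fixture dump. It
emulates, with planted ground truth:

* **Reference genomes**: uniform-random ACGT chromosomes carrying
  non-overlapping genes (5′UTR, 2–4 exons, canonical GT..AG introns,
  ATG-initiated stop-terminated CDS divisible by 3 with no internal
  stop, 3′UTR), on random strands, with ≥1.5 kb intergenic gaps so
  planted flank edits of neighbouring genes stay out of each other's
  alignment windows.
* **Pangenome members**: the reference with one planted edit per
  (gene, member) cell drawn from nine classes — non-synonymous,
  synonymous (verified against the codon table at planning time, with
  re-draws and a hard failure after 100 attempts), frameshift indel,
  in-frame indel, UTR substitution, intron substitution, flank
  substitution, whole-gene deletion, or none. Each class maps to the
  pairwise classification the cascade must recover; the truth table
  records both the per-pair verdicts and the implied gene categories.
* **Marker panels**: markers placed uniformly; within blocks of a given
  length, genotypes copy a shared latent haplotype pair with per-marker
  flip noise, giving tunable within-block LD; blocks are independent.
  This block-copy model is deliberately simpler than coalescent
  simulation: it is sufficient to exercise decay estimation and orders
  of magnitude cheaper. Setting the block length to 1 bp yields fully
  independent markers for scan calibration.
* **Phenotypes**: trait = Σ effect × dosage + Gaussian noise scaled so
  the genetic variance fraction matches the requested heritability; an
  empty effect map produces pure-noise traits for null calibration.

What the generator does *not* emulate — hexaploid subgenome structure,
repeats, realistic base composition, genotype-calling error modes, and
kinship — bounds what passing tests demonstrate: the pipeline's logic
and numerics are validated exactly; its statistical behaviour on real,
structured camelina panels is not certified by these tests.

Diploid-style dosages are used throughout, matching how the motivating
study's VCFs treat the hexaploid: markers are called against a single
reference and handled as diploid genotypes.

# Numerical and validation choices

Validation problem sizes were chosen to exercise every code path at
desk scale: the classifier truth-recovery run uses 45 genes × 12
members (540 planted events covering all nine classes, 100% agreement
required); alignment scores are cross-checked against an independent
dynamic-programming implementation on sequences up to 200 bp; interval
merging is checked against a union-find oracle on 1,000 random
instances; LD recovery uses 400 markers in 25 kb blocks over 200
accessions, with the half-width required to land within one 5 kb bin of
the planted block length; scan calibration uses 150 independent markers
× 200 accessions with Bonferroni α = 0.05 (empty on null traits; three
planted signals recovered in ≤ 3 iterations; planted effect 1.0
recovered within ±0.25 at heritability 0.8).

Determinism is part of the contract: identical seeds give byte-identical
FASTA/GFF3/VCF output, identical manifests (minus timestamps), and
identical classification tables; all tie-breaks are explicit.

# Known limitations

Only the longest transcript per gene is analysed (no isoform handling);
no dN/dS estimation; the OLS test does not model kinship; the search
has no composition-adjusted scoring, so highly repetitive references
would need masking upstream; and the published genome-scale totals of
the motivating study (which require the real panel genotypes, assembly
and pangenome) are out of reach by construction — the package validates
the *machinery* on its self-contained worked numbers and planted truth
instead.
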