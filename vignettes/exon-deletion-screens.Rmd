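---
title: "Models and methods for single-cell exon-deletion screen analysis"
author: "scExonScreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for single-cell exon-deletion screen analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistical models it
implements, the parameters that matter, the numerical choices taken where
the design was genuinely open, and what the synthetic-data generator does
and does not emulate. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

# The screen and its data

A dual-nuclease exon-deletion screen expresses, in each cell, one hybrid
guide RNA (hgRNA) that is processed into a Cas9 guide and a Cas12a guide.
For exon-deletion hgRNAs the two guides cut the introns flanking an
alternative cassette exon, excising it; gene-knockout hgRNAs direct both
nucleases into coding sequence; intergenic hgRNAs cut a gene-free locus
and are the baseline class for every comparison; non-targeting hgRNAs cut
nothing and are excluded from analysis. Droplet-based scRNA-seq captures
each modality's guide through its own capture sequence, giving per cell a
guide-UMI matrix split into Cas9 and Cas12a features plus a gene-expression
UMI matrix. The package's data containers follow Bioconductor conventions:
the expression matrix is a `SingleCellExperiment` (genes × cells) with the
guide-capture matrix as an `altExp`, the library manifest is a
`GuideLibrary`, and per-cell assignment state is a `CellAssignment`.

# Guide assignment

A guide is *detected* in its modality when its UMI count reaches
`min_umi` (default 5) and — when it is the only guide above `min_umi` —
also exceeds `dominance_ratio` (default 3) times the next-highest guide of
that modality. When several guides of one modality clear `min_umi` they
are all reported, so that doublets stay visible. The two defaults are
deliberately conservative; upstream counting tools do not publish their
thresholds, so both are explicit parameters rather than inferred values.

Assignment logic: a cell is *assigned* when all detected guides are
consistent with exactly one library hgRNA. A single modality detecting a
single guide is accepted as evidence (configurable: `require_dual`),
because dual detection rates are a property of capture efficiency, not of
identity. Cells with ≥2 distinct hgRNAs in one modality are *doublets*.
Cells whose Cas9 and Cas12a guides belong to different hgRNAs with no
single-hgRNA explanation are *decoupled* — template switching during
library cloning or packaging can swap guide pairings, which makes the
cell's true perturbation unknowable; decoupled cells are therefore
dropped, never reassigned. Capture categories (dual / Cas9-only /
Cas12a-only / none) are summarised under two normalisations: over all
cells and over cells with at least one detected guide.

# QC and the normalisation chain

Filters run cell-first, then gene (single pass; an iterate-to-fixed-point
mode exists): cells with fewer than 200 expressed genes and genes
expressed in fewer than three cells are removed — both thresholds are
exact boundaries (a 200-gene cell stays). Counts are scaled to 10,000 per
cell and log1p-transformed. Highly variable genes are selected by the
dispersion method: per gene the mean and variance/mean of
`expm1(normalized)` values, dispersions z-scored within 20 equal-frequency
mean bins, flagged when the mean lies strictly inside (0.0125, 3) and the
z-scored dispersion exceeds 0.5. Equal-frequency bins are defined as
consecutive chunks of the mean's rank order
(`ceiling(rank * n_bins / n)`); this makes the partition reproducible from
the sort order alone, which the test oracles exploit. Total UMI count and
mitochondrial percentage (genes matched by the `"MT-"` prefix by default)
are regressed out per gene by OLS; residuals are centred, scaled to unit
variance and clipped at +10 — the upper tail only, since the stated limit
is an upper one. Genes whose residual variance is numerically zero
(relative tolerance 1e-10) are set to zero rather than amplified.

# Perturbation signature and escaping cells

Not every cell carrying a guide is actually perturbed: lentiviral
silencing, incomplete editing or in-frame repair leave *escaping* cells
whose transcriptome is control-like. Retaining them dilutes every
downstream phenotype, so cells are classified before phenotype calling.

The *local perturbation signature* of a cell is its scaled expression
minus the mean of its `n_neighbors` (20) nearest control cells, with
neighbors found in `n_pcs` (40) principal components of the scaled layer
(restricted to HVGs when at least 20 are flagged; with fewer, the package
falls back to all genes, since a near-empty signature space is
degenerate). Control cells exclude themselves from their own neighbor
sets. Subtracting matched controls cancels shared cell-state variation —
notably cell-cycle position — and leaves the perturbation-specific shift.

Per target, cells are scored by projecting their signatures onto the
difference vector between the mean target signature and the mean control
signature. Projections are leave-one-out: a cell never contributes to a
mean it is scored against. Without this correction every null target
looks separated, by roughly `sqrt(G (1/n_t + 1/n_c))` standardised units
(G = genes in the signature space) — an artefact of projecting noise onto
its own average. A two-component univariate Gaussian mixture is then fit
to the scores with one component anchored on the control score
distribution; the free component is initialised from a 2-means split of
the target scores (the cluster farther from the control mean) and updated
by EM (tolerance 1e-4, at most 100 iterations). Cells whose posterior for
the free component exceeds 0.5 are *perturbed*; ties go to escaping — the
conservative direction, since a false "perturbed" label manufactures
phenotype.

A target is declared *undetectable* — all cells escaping — when the
standardised separation falls below 0.5. The declared minimum is applied
to two quantities and the smaller decides: the distance between the two
fitted component means (in pooled-sd units) and the standardised
difference between the target and control score distributions. The second
guard exists because an anchored EM on a genuinely null target can
converge to a local optimum describing a noise tail, with an apparent
component separation above 0.5 even though the target and control score
distributions are nearly identical. Targets with fewer than 10 cells are
flagged unclassifiable and fully retained with a warning. The escape rate
of a target is the fraction of its cells classified non-perturbed.

# Pseudobulk differential expression

Single-cell counts are summed within groups — one group per guide, so
that independent guides act as biological replicates (three per exon, two
per knockout, 40 intergenic groups as the control side). Groups under
`min_cells` (10) are dropped. Where perturbed-cell flags exist,
aggregation uses perturbed cells only (controls always kept); this is the
default, configurable.

The count model is the negative binomial. Size factors are
median-of-ratios: for group *j*, the median over reference genes of
`count_gj / geometric-mean_g`, the reference being genes with no zero in
any group (fallback: positive-count genes per group, with a warning). The
median is taken in ratio space — exactly the stated formula; log-space
medians differ only in interpolation at even gene counts. Per-gene
dispersions come from the method of moments on normalised counts,
`(s² − q̄)/q̄²`, shrunk toward a mean–dispersion trend fitted by loess on
the log scale (span 0.5, robust family): the final dispersion is the
geometric mean of the gene-wise estimate and the trend, with nonpositive
gene-wise estimates taking the trend and a floor of 1e-8. Testing fits,
per gene, an NB log-linear model with a condition indicator, log size
factors as offset and the dispersion fixed at the shrunken estimate, and
applies a Wald test to the condition coefficient (reported on the log2
scale). Genes with mean normalised count below 1 are excluded before
Benjamini–Hochberg adjustment (independent filtering; configurable).
Numerically perfect fits (Wald SE below 1e-8) report p = 1: identical
profiles carry no evidence. A DEG has `padj < 0.05` and `|log2FC| > 0.5`.

Guide concordance for a target is the mean of all pairwise Pearson
correlations of per-guide log2FCs over the highly variable genes. The
same Wald engine serves the guide-level pass; only the log2FC profile is
consumed there, so no second test framework is introduced.

# Cell-cycle phases and enrichment gates

The S and G2/M program scores subtract an expression-matched control
pool: all genes are binned into 25 equal-frequency bins of mean
expression and 50 control genes are sampled (seeded, without replacement
within a bin) from the bin of each program gene. A cell is G1 when both
scores are ≤ 0, otherwise the larger score wins; an exact S = G2M tie
goes to G2M, matching the `if s > g2m then S else G2M` convention.
Standard S (43 genes) and G2/M (54 genes) marker lists ship under
`inst/extdata/`; any list can be supplied.

Phase redistribution is tested per target and phase with a one-sided
(enrichment) alternative — the screens report *increased* phase fractions.
Two levels of evidence are combined for exon targets:

* **Cell level** — Fisher's exact test on the 2×2 table of in-phase vs
  out-of-phase cells, target vs all intergenic cells pooled.
* **Replicate level** — Mann–Whitney comparing the target's per-guide
  phase fractions (n = number of guides) against the intergenic
  per-group fractions (n = 40), normal approximation with tie correction
  and no continuity correction.

Each test's p-values are BH-adjusted across all (target, phase) pairs of
the run — the family is per test type, a choice this package declares
since only the correction method is stated upstream. An exon's phase is
significant only when `fisher_padj < 0.01` **and** `mw_padj < 0.05`
(the dual gate); knockouts use the Fisher gate alone at 0.01, because the
replicate-level test with two guides has essentially no power. When two
phases pass, the called phase is the one with the lowest adjusted
p-value; with two adjusted p-values per phase the package ranks by the
Fisher adjusted p (the gate shared by both modes) and breaks ties by the
Mann–Whitney adjusted p. Exon targets with fewer than two guides are
unassessable under the dual gate and reported as such. The asymmetry —
cells pooled for Fisher, group fractions for Mann–Whitney — is
deliberate: the two tests contribute different levels of evidence, and
the Mann–Whitney on guide fractions is this package's reading of the
replicate-level comparison, recorded in the run manifest.

# Exon-versus-knockout divergence

Deleting one exon should often phenocopy knocking out its host gene; the
interesting exons are those where it does not. The concordance of an exon
with its knockout is the Pearson correlation of log2FCs over the union of
the two comparisons' DEGs (the union is the declared gene set; profile
clustering across perturbations instead uses genes that are DEGs in at
least 30 perturbations, with average-linkage hierarchical clustering on
1 − r — the linkage is unstated upstream and declared here). An exon is
concordant when r strictly exceeds 0.4; r = 0.4 exactly is not
concordant. The genes differentially expressed in the *direct*
exon-versus-knockout comparison form the divergent set. Because both
perturbations can shift cell-cycle composition to different degrees,
`phaseConditionedDE()` recomputes the pseudobulk comparison within one
phase (typically G1): differences that were purely composition-driven
vanish there, while direct regulatory differences persist.

# Exon annotation

Coordinates are GTF convention throughout: 1-based, inclusive.
*Inclusion* transcripts contain an exon with exactly the targeted start
and end (overlap is not enough — alternative 5'/3' splice-site variants
must not be misattributed); *skipping* transcripts have an intron
spanning the whole exon. The *deleted coding length* is the overlap of
the exon with the transcript's CDS; the deletion is frame-preserving when
that length is a multiple of 3 (a fully-UTR exon deletes 0 coding bases
and preserves frame trivially). A skipping transcript is *strict* when
its coding sequence equals an inclusion transcript's with exactly the
targeted exon removed; for mutually exclusive exon (MXE) pairs the
partner exon is substituted instead. Strictness is judged on coding
sequence only — UTR differences do not disqualify, a reading this package
fixes where the upstream description is ambiguous. Without a genome FASTA
the comparison is made on CDS coordinates (coordinate identity implies
sequence identity); with a FASTA the reconstructed nucleotide sequences
are compared, which additionally accepts coordinate-different but
sequence-identical cases. The *longest* skipping transcript is the one of
maximal total exonic length, irrespective of other differences.

# The synthetic-data generator

The generator is first-class, tested code; its defaults are the study
conditions the package models. Library composition: 224 exon targets × 3
guide pairs, 161 gene targets × 2, 40 intergenic + 40 non-targeting
controls (the counts are parameters — the deposited library's curated
total differs from the design arithmetic by a handful of guides, so
nothing is hard-coded). Per cell: detection probabilities 0.97 (Cas9) and
0.95 (Cas12a), chosen so that dual detection is ≈92%, matching the
reported detection rate of the optimised capture chemistry; detected
guides receive `1 + Poisson(20)` UMIs; ambient background adds
`Poisson(0.1)` UMIs to at most two random guide features, giving the
detector something to threshold. Doublet rate 0.08 (typical for droplet
loading at these cell numbers); doublets sum two cells' expression and
emit both hgRNAs. Decoupling rate 0.05: the Cas12a guide is swapped for a
random other hgRNA. Expression is NB with log-normal baseline means,
dispersion 0.2 (a typical pseudobulk-scale value), per-cell log-normal
library-size factors (sdlog 0.3), per-target log2FC programs
(Poisson-sized affected sets; effect magnitudes uniform in
`lfc_scale × [0.5, 1.5]` with random signs, so a null library is
`lfc_scale = 0`), an escaping fraction (default 0.2) of cells that keep
baseline means, and phase-structured markers: each cell draws a phase
from (G1 0.18, S 0.52, G2M 0.30) — matching the ~17–18% G1 observed in
control cells of rapidly dividing near-haploid lines — and its own-phase
markers gain `phase_effect_lfc` (default 1.0) log2 units.

What it does *not* emulate: ambient mRNA contamination, batch structure
across GEM wells, UMI saturation, guide-abundance skew, per-guide editing
efficiency differences (escape is i.i.d. per cell), doublets of unequal
RNA content, and any dependence of expression on deletion genotype beyond
the planted log2FC program. Passing tests therefore demonstrate that the
algorithms recover the structure they assume, at the stated sizes — not
that real screens satisfy those assumptions.

# Numerical choices and problem sizes

Determinism: every stochastic function takes a seed and restores the
caller's RNG state; `runPipeline()` fans a single seed out to per-stage
child seeds through a stage-name hash, so disabling one stage does not
shift another's stream, and seeded runs are bit-identical. Degenerate
inputs are handled explicitly: empty matrices filter to an empty object
with a warning (not a crash); zero-count cells are an error at
normalisation (they should have been filtered); all-zero genes are
excluded from DE; empty DEG unions make concordance unassessable; a
missing CDS makes frame calls unassessable rather than false.

The test suite and acceptance script run the heavier checks at sizes
chosen to exercise the asymptotics the properties rely on while staying
desk-scale: 5,000 cells for noise-free assignment recovery, 10,000 for
capture-category calibration, 200 cells per group × 43 pseudobulk groups
for DE recovery, 500 null and 100 shifted targets for the dual gate's
calibration and power, and 200 cells per target for escape-rate
recovery. Screen-scale headline numbers (hundreds of thousands of cells)
require the deposited data and are out of scope for the synthetic
benchmark.

# Known limitations

* The escape-rate estimator is slightly conservative: with a strong
  effect and 30% simulated escapers it recovers ≈0.32–0.37 (the mixture
  assigns a few genuinely perturbed boundary cells to the control
  component). The property tests bound this error at ±0.1.
* Mixture classification needs a detectable transcriptional effect;
  weakly-acting exons are declared undetectable and their cells retained
  as escaping, which removes them from phenotype calling rather than
  risking false phenotypes.
* The NB Wald test with guides as replicates inherits the usual caveat
  of few-replicate designs: dispersion shrinkage is what makes it
  usable, and outlier handling (e.g. Cook's-distance replacement) is
  deliberately not implemented.
* The annotation module trusts the GTF: unannotated isoforms, and ORF
  changes arising outside the targeted exon (e.g. induced downstream
  start codons), are out of scope.
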