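---
title: "Nucleosome occupancy from Strand-seq: models and methods"
author: "strandNO authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nucleosome occupancy from Strand-seq: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strandNO)
library(GenomicRanges)
library(SummarizedExperiment)
```

## The measurement model

Strand-seq libraries are built from MNase-digested DNA, so each sequenced
paired-end insert is one nucleosome-protected fragment, typically 140-180 bp.
Counting how many fragments cover a base pair therefore measures nucleosome
occupancy (NO) directly: high NO marks closed chromatin, and transcribed gene
bodies show depleted NO. Because the libraries are directional, each read
also carries the identity of the template strand it came from (Watson, W, or
Crick, C), and chromosomes inherited in the mixed W/C configuration in a cell
let reads be assigned to a chromosomal homolog (H1/H2) along their entire
length. These two properties drive everything in this package:

* **global readout** -- gene-body NO count matrices (all reads, phased or
  not) act as an inverse proxy for gene activity, supporting cell typing and
  clone-versus-clone differential activity tests;
* **local readout** -- phased counts from mixed-state (WC) chromosomes give
  haplotype-specific NO, which exposes the cis effects of structural
  variants (SVs) on the rearranged homolog.

NO here is always the *mean per-bp fragment coverage* within a bin or
feature (the bin statistic is a mean, not a sum), with no peak calling or
smoothing. Fragments are full insert intervals; QC removes records with
MAPQ < 10, duplicates and supplementary alignments, plus anything touching a
user-supplied blacklist by at least 1 bp. Coordinates are 0-based half-open
on disk (BED convention) and ordinary 1-based `GRanges` in memory; W maps to
the `-` genome strand and C to `+` (only relative consistency matters
downstream).

## Template-strand states

Each (cell, chromosome) pair is classified from its Watson fraction:
`WW` at or above `upper` (default 0.8), `CC` at or below `lower` (default
0.2), `WC` (mixed) in between, and `UNKNOWN` below `min_fragments` (default
20). These numeric cutoffs are deliberate configuration -- no published
values exist for them -- and the two mixed orientations are collapsed into a
single `WC` label because every downstream consumer needs only the
mixed-versus-pure distinction; homolog identity travels with the per-read
haplotype tags, not the state label.

## Counting and normalization

`geneBodyCounts()` counts fragments overlapping each gene body (TSS to
transcription termination site) by at least 1 bp; a fragment spanning two
genes counts in both. The per-cell library size is the total number of
retained fragments, not only in-gene fragments -- the usual library-size
semantics. `normalizeCounts()` composes three individually skippable steps:

1. copy-number normalization, `count * 2 / CN`, with the gene-level CN
   chosen by majority overlap of the gene body with the relevant segments
   (ties go to the lower-coordinate segment; CN = 0 with nonzero counts is
   floored at a pseudo-CN of 0.5 and logged rather than raised);
2. reads per million over the library size;
3. `log2(x + 1)` -- the pseudocount of 1 is this package's choice, since the
   transform is conventionally stated without one.

Batch adjustment is location-only on the log scale: per gene, each batch is
recentered to the gene's grand mean. A full count-model batch correction is
deliberately out of scope; the function boundary allows swapping in an
external tool. Batches with fewer than two cells pass through with a
warning.

Anchor-averaged profiles (for example around bound CTCF sites) average
per-bp coverage across anchors after flipping minus-strand anchors, then
scale the profile so the bin at offset -2000 bp equals 1 -- the standard
convention for such plots; scaling fails loudly if that bin has zero
coverage.

## Cell typing: PLS-DA with VIP selection

`fitPlsda()` is a NIPALS PLS2 regression of centered dummy-coded class
labels on standardized gene-body NO features. The fit is deterministic given
input ordering (the inner iteration starts from the largest-variance dummy
column), requests for more components than the data rank are reduced with a
warning, and training standardization parameters are reused verbatim at
prediction so there is no leakage. Feature selection keeps features with
variable importance in projection (VIP) above 1 on an initial full fit,
followed by a refit; VIP scores satisfy `sum(vip^2) = G` by construction, so
1 marks an average contribution. The published feature-selection outcome
count exists but not its method; VIP > 1 is this package's documented
choice. Multi-class problems use one dummy column per class with argmax
decisions and macro-averaged one-vs-rest AUC.

## Differential gene activity

The two-step module compares two cell populations (clones):

**Step 1 (NE filter).** Genes unlikely to be expressed in *any* clone are
removed: a gene is dropped iff its probability of the not-expressed state is
at or above 0.9 (inclusive) in every clone. The classifier consumes, per
gene, 150 equal-width bins of gene-body NO, 150 per-bin GC fractions and the
log gene length. The reference implementation of this classifier is a small
1-D convolutional network whose exact architecture is not publicly
specified; this package implements the same probability contract with a
ridge-regularized logistic model (deterministic at a fixed penalty, default
0.01), with an unregularized `glm` engine for low-dimensional feature sets.
The contract -- a probability in [0, 1] per gene per clone and the 0.9
across-clones filter -- is what downstream code relies on.

**Step 2 (differential test).** The default is a per-gene negative-binomial
GLM `log mu = log s_j + b0 + b1*[clone 2]` with median-of-ratios size
factors and a two-sided Wald test of `b1 = 0`. Fitting is IRLS with
convergence tolerance 1e-8 and at most 100 iterations; non-convergence and
genes where either group is all-zero are flagged `NA` rather than failing.
Dispersions (`variance = mu + alpha*mu^2`) come from a documented
method-of-moments estimator on size-factor-normalized counts, floored at 0,
with no empirical-Bayes shrinkage toward a trend -- re-deriving a shrinkage
estimator is out of scope, and the estimator's calibration is covered by
tests (Poisson data recover alpha near 0; NB data with alpha = 0.5 recover
it within [0.3, 0.7] at 100 cells). The *differential gene activity score*
is `sign(log2 FC) * (-log10 p)`, and significance is BH FDR < 0.1
throughout.

For minor clones below 10% clonal frequency the Wald test loses power, and
`diffGeneActivity()` switches (configurably, `cf_mode_switch = 0.1`) to the
PLS-DA alternative mode: each gene's VIP from a PLS-DA of the clone labels
is the statistic, and its p-value comes from label permutations,
`p = (1 + #{perm VIP >= obs}) / (n_perm + 1)` (default `n_perm = 1000`; all
distinct assignments are enumerated instead when fewer exist). Fold changes
in this mode are differences of group means on the log2-normalized matrix.

Genes whose total copy number differs between the compared clones over at
least 1 bp of the gene body are masked before testing, since CN differences
would confound differential NO.

## Haplotype-specific analyses

Phased counts are accumulated per unit (gene, window or CRE) from cells
whose chromosome is in the WC state, normalized by per-haplotype copy
number. The genome-wide test is an **unpaired** two-sided Wilcoxon rank-sum
comparison of per-cell H1 values against per-cell H2 values (the published
wording names the rank-sum test; a paired signed-rank variant sits behind
`paired = TRUE`), with at least 5 informative cells per unit and BH
correction. The effect is `log2((mean H1 + 1) / (mean H2 + 1))`; swapping
the haplotype labels inverts the fold change and leaves p unchanged.

Around each SV breakpoint, `localScan()` selects genes within a 1 Mb radius
and re-adjusts p-values by BH within that scan set only. The
sliding-window profile (defaults 50 kb windows, 10 kb step -- the published
analysis states no sizes, so these are configuration) pools phased counts
per window and tests the H1 proportion against `p0` with a binomial
likelihood-ratio chi-square; the analytic p is then adjusted by permuting
the haplotype labels of all phased fragments in the region (per-window
totals are preserved automatically since positions are fixed). The window
fold change is the plain ratio `n_H1 / n_H2` when both counts are positive;
a pseudocount of 1 is added to both counts only when one of them is zero,
keeping the FC finite and positive without biasing informative windows.
"Exact test" at CREs is realized as a two-sided exact binomial test of the
pooled H1 count against the copy-number expectation
`p0 = CN_H1 / (CN_H1 + CN_H2)` -- the test is named but not defined in the
published description, and the exact binomial is the natural reading for
pooled phased counts. TAD-level outliers use a two-sample KS test of log
fold changes of windows inside each TAD against windows in all other TADs,
requiring at least 3 windows per side.

## Gene sets and pathways

Over-representation of gene sets (for example transcription-factor target
lists) among differentially active genes uses the upper-tail hypergeometric
test (equivalently one-sided Fisher) within the tested universe, BH at 10%.
Pathway-level NO is the per-cell mean of median-of-ratios-normalized counts
over the pathway's members after removing lowly variable genes. The
published filter, "s.d. < 80%", is ambiguous; the default here drops genes
below the 80th percentile of the across-cell s.d. distribution, with an
absolute-threshold alternative behind `mode = "absolute"`. Pathway activity
for display is `(-1) * Z` of NO across cells, so that low occupancy reads as
high activity. The SV-status test is a maximum-likelihood linear mixed model
(`score ~ SV + (1 | batch)`) against the nested null by likelihood-ratio
test on one degree of freedom -- ML rather than REML so the LRT is valid,
and no boundary correction since the tested term is fixed. A single batch
degenerates gracefully to an ordinary linear-model LRT (logged).

## The synthetic-data generator

`simulateGenome()` / `simulateCells()` emulate the features of real
Strand-seq data that the inference depends on:

* mono-nucleosomal fragments, lengths uniform on 140-180 bp, midpoints on a
  nucleosome lattice (repeat 190 bp, Gaussian jitter s.d. 20 bp) so
  anchor-averaged profiles oscillate;
* per-(cell, chromosome) template states from an independent fair coin per
  homolog (WW/CC/WC at 1/4, 1/4, 1/2), with every fragment's strand
  following its homolog's template;
* expression-linked NO: silent gene bodies carry `no_depletion_factor`
  (default 2) times the per-bp rate of expressed genes, with a continuous
  expression level modulating the depletion -- 2x is a realistic contrast
  between strongly expressed and silent genes in MNase-type data;
* SV clones at configured clonal frequencies: heterozygous deletions
  suppress the deleted haplotype's fragments, duplications scale the
  haplotype rate by its copy number, and per-gene clone/haplotype NO factors
  implant known differential and allele-specific effects;
* library-size variation (negative-binomial totals, mean 2000 fragments per
  cell, size 10) and additive log2 batch effects;
* full truth tables: clone, batch, template states, expression states, and
  each fragment's haplotype of origin. By default every fragment keeps its
  haplotype tag; `unphased_fraction` strips a configurable share to
  UNPHASED to emulate realistic (~50%) phasing rates.

What the generator does **not** emulate: real sequence content (GC features
are simulated values), mappability artifacts, chromatin-state heterogeneity
beyond the expressed/silent contrast, read-level error, or SV classes with
complex geometry (inversions and translocations are carried through the
tables but do not reshape fragment sampling). Passing tests on this
generator therefore demonstrate correctness of the statistical machinery
under the stated model -- calibration, sensitivity at known effect sizes,
label symmetries, conservation laws -- not performance on real libraries,
where fragment counts, phasing rates and confounders are less favorable.

## Numerical choices and degenerate inputs

* IRLS: tolerance 1e-8, 100 iterations, flagged `NA` on non-convergence.
* NIPALS: tolerance 1e-10 on the weight vector, components capped at the
  data rank, zero-variance features kept with unit scale (they contribute
  nothing).
* Permutation p-values always include the observed statistic
  (`(1 + k) / (n + 1)`), so they are bounded below by `1/(n_perm + 1)` and
  never zero.
* Median-of-ratios reference genes must be positive in every cell; sparse
  matrices can opt into a positive-counts pseudo-reference
  (`pseudoReference = TRUE`), which the pipeline uses as a logged fallback.
* Gene-to-CN-segment assignment: majority overlap, ties to the
  lower-coordinate segment.
* Constant vectors make rank correlation undefined: flagged `NA` with a
  warning, not an error.
* All randomness in the pipeline and simulator flows from a single integer
  seed; reruns are byte-identical.

## Problem sizes used by the test suite

The packaged studies are sized to run on one CPU in minutes: NB-GLM
calibration and recovery use 200 genes by 2 x 50 cells; the haplotype
recovery study uses 60 genes by 64 cells at 2000 fragments per cell (64
cells keep the median number of informative WC cells per gene at or above
20, the regime the sensitivity claim is about); PLS-DA checks use 3-class
mixtures (60 cells in the unit tests, 120 in the acceptance script, where
half are held out for the permuted-label chance-level estimate). These sizes are the package's chosen study conditions, and
the acceptance script re-runs the same computations from scratch.

## Known limitations

* The NE classifier is a linear model on binned NO and GC; it honors the
  probability contract but is not a reimplementation of the reference CNN,
  and users with matched expression data should retrain on their own labels.
* Dispersion estimation has no shrinkage: per-gene estimates are noisy at
  few cells, which the Wald test inherits.
* Batch adjustment is location-only; strong batch-by-gene interactions are
  not corrected.
* Haplotype analyses need WC-state chromosomes and phased tags; chromosomes
  that happen to be pure-state in most cells yield few informative cells and
  `NA` results rather than estimates.
* The sliding-window permutation shuffles haplotype labels within the
  scanned region, which assumes exchangeability of phased fragments across
  the region under the null; strong regional CN structure should be encoded
  via `p0` instead.
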