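---
title: "Methods: sex-differential methylation and methylation QTL on the Z chromosome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sex-differential methylation and methylation QTL on the Z chromosome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zmethqtl)
```

This vignette documents the models behind each stage of the pipeline, the
parameters that matter, what the synthetic-data generator does and does not
emulate, and the design choices made where the methodology was genuinely
open. It states no empirical result beyond what the test suite and
`scripts/acceptance.R` themselves compute.

## Window phenotypes

Methylation phenotypes are read counts in fixed 1-kb windows, 0-based and
half-open (`[start, start + 1000)`, labelled `chrom_start`). Half-open
windows are the convention under which a block spanning windows
`start .. last_start` has size `last_start + 1000 - start`, which is how the
bundled block tables are sized. Counts are normalized per individual by
dividing by that individual's total read count and multiplying by a scale
constant (`scale`, default $10^6$, counts-per-million-like). The absolute
scale of published per-window thresholds depends on an unstated calibration,
so every level threshold in this package (notably the MHM median floor,
default 8.52) is a configuration value in the same units as the chosen
scale, not a constant. Raw totals are retained so `denormalize_methylation()`
recovers counts exactly; per-individual normalized values sum to `scale` by
construction. Zero counts are treated as genuine zeros; missingness is not
modelled.

## Sex-difference scan and block calling

Each window is tested male-versus-female with a two-sided Wilcoxon rank-sum
test: exact enumeration when both groups have fewer than 8 observations and
no ties, otherwise the normal approximation with tie and continuity
correction. At the study's group sizes (69 vs 55) the approximation is the
operative branch; the exact branch keeps the statistic testable against
brute-force enumeration on toys.

A male hyper-methylated (MHM) block is a maximal run of strictly adjacent
windows (start-to-start distance exactly one window size — a single failing
window breaks a run) that each satisfy `mf_ratio > 1`,
`median > median_min` and `p < p_max`, with at least `min_run = 5` windows.
Defaults for the male direction are the calibration that recovers the
original MHM region (`median_min = 8.52`, `p_max = 1.75e-10`). The female
(FHM) direction uses unadjusted `p < 0.05` with `mf_ratio < 1` and no median
floor: published FHM windows include p-values as large as ~0.03, so a
stricter or adjusted threshold could not reproduce them. The block p-value
threshold is applied to raw, unadjusted p-values.

Genes are attached to blocks within a 100-kb flank, closed at the boundary
(a gene exactly 100,000 bp away is included). Gene-level sex-difference
p-values in block reports are Holm-adjusted across the report's genes and
capped at 1 — the capped adjustment is what reproduces the many `1.00E+00`
entries of the bundled gene table.

## Genotype probabilities and Haley–Knott scans

Conditional genotype probabilities on a pseudomarker grid (default step:
1 cM; the mapping wrapper uses 2 cM) follow a Markov model along each
chromosome with Haldane recombination fractions
$r = \tfrac12(1 - e^{-2d/100})$. Autosomes and the male Z have three dosage
states with the F2-style transition matrix built from independent haplotype
switches; the hemizygous female Z has two states. At a typed marker the
distribution is degenerate on the observed genotype; between markers it is
the normalized product of the flanking transition rows, and beyond terminal
markers the single-sided transition row. Missing genotypes defer to the
nearest typed flanking markers. No advanced-intercross map expansion is
applied: the probabilities are conditional on flanking observed genotypes,
which already carry the accumulated recombinations.

The scan regresses the phenotype on expected dosages (Haley–Knott) with sex
and batch covariates; `LOD = (n/2)\log_{10}(RSS_0/RSS_1)` with the null
retaining the covariates. The interactive model adds a genotype-by-sex
term. Cross-sex pooling on the Z uses the additive dosage column only
(female dosages live in `[0,1]`, male in `[0,2]`), with sex always in the
model; no dominance column exists for the female Z. A constant phenotype is
defined to have LOD 0 everywhere. The implementation residualizes the
dosage columns against the covariates once and solves the per-position 1-
or 2-parameter normal equations in closed form, which makes permutation
scans cheap; it is tested to $10^{-8}$ against explicit least squares.

**Sex-interaction flag.** A locus is sex-interactive when the best
interactive fit exceeds the best additive fit by strictly more than 1 LOD
(`8.1 − 7.0` fires; `8.0 − 7.0` does not). The two curves' maxima are
compared by default rather than both models at the additive peak: a locus
whose per-sex effects cancel in the pooled additive fit has no meaningful
additive peak, and comparing at the interactive maximum alone inflates the
null flag rate through argmax selection. The maxima comparison is the
reading that is simultaneously powerful and calibrated in the acceptance
simulations.

**Permutation thresholds.** For each sampled phenotype, individual labels
are permuted `n_perm` times, the genome-wide maximum LOD recorded per
permutation, and the phenotype's top 5% of maxima kept; kept values are
pooled across phenotypes, with the significant threshold the 95th percentile
of the pool and the suggestive threshold the 80th. The published
description is ambiguous between pooling per-phenotype maxima and pooling
all per-position scores; the per-phenotype-maxima reading is implemented
because genome-wide maxima are the quantity a significance threshold must
bound. Permutation is free by default with sex retained as a covariate in
the scan; within-sex stratified permutation is available
(`stratify_by_sex = TRUE`). At least 20 permutations are required or the 5%
tail is empty.

**Cis/trans and QC.** A QTL is cis when its peak lies on the phenotype's
chromosome within 50 cM (closed boundary) of the phenotype's interpolated
genetic position (linear bp-to-cM interpolation between flanking markers,
clamped at chromosome ends); a peak on another chromosome is trans;
phenotypes without coordinates are unplaced. Records with fewer than 10
individuals in any genotype class at the peak marker are dropped (10
exactly is retained). Outlier-driven peaks are flagged by an automated
surrogate for visual inspection: the most influential observation (largest
|DFFITS| in the peak-marker fit) is removed and the peak LOD refit; falling
below the applicable threshold flags the record. Support intervals use a
1.5-LOD drop — the widest contiguous interval around the peak with LOD
within 1.5 of the maximum — expanded outward to the nearest flanking typed
markers for bp reporting; the source study reports interval bounds without
stating its method, and 1.5-LOD is the standard choice at this marker
density.

## Trans hotspots

Trans QTL are grouped by peak marker; groups at consecutive markers are
merged when every pairwise member-interval overlap is non-empty (equivalent,
in one dimension, to a non-empty common intersection), because published
hotspots include one spread over three adjacent SNPs without a stated merge
rule. Groups with at least `min_count = 10` members are hotspots; the
member-count threshold is applied after merging. The reported span is the
intersection of member support intervals `[max(lows), min(highs)]`; an
empty intersection falls back to the union with a warning rather than an
error, since the degenerate case is not addressed in the source
methodology. Mean spans are reported in Mb at 2 dp.

## Methylation–expression integration and causal orientation

Overlapping (eQTL, methQTL) pairs — same chromosome, support intervals
overlapping with closed endpoints — are tested by regressing expression on
methylation under three models: all individuals with sex as a factor, males
only, females only, with Benjamini–Hochberg FDR within each model family. A
stratum under 3 usable individuals is untestable (NA).

Significant pairs are oriented with a single-anchor SEM comparison over
$(G, E, M)$ — the shared QTL genotype dosage, expression, methylation. The
seven directed orderings listed in the source methodology collapse, once
both QTL share one genotype anchor, to five distinct path models:
$G \to E \to M$, $G \to M \to E$, $E \leftarrow G \to M$ (independent given
G), $G \to E \leftarrow M$ (with $G \perp M$), and
$G \to M \leftarrow E$ (with $G \perp E$). Each is a Gaussian path model
fitted by maximum likelihood on the 3×3 covariance structure (genotype
treated as observed numeric dosage; variances parameterised on the log
scale; BFGS from moment-based starts; each model has 5 free parameters
against 6 moments, hence 1 df), scored by its $\chi^2$ goodness-of-fit
p-value. `LEO.NB.OCA = log10(p_best / p_second_best)`; above 1.0 is
significant, above 0.8 suggestive, and the orientation is the best model's
edge direction. LEO.NB.CPA is reported equal to OCA — in the single-anchor
case the two scores coincide, as the published causality table's identical
columns reflect. When the best model's own fit p-value is below 0.05 a
caveat flag is set: a poorly fitting winner does not rule out competing
models. The construction makes the procedure antisymmetric under swapping
E and M (the two chain models and the two collider models exchange fits).

## The synthetic-data generator

The generator emulates the study design: one wild founding male crossed to
three domestic founding females, random mating to the 8th generation
(intermediate population size `pop_size = 200`), and a final sample of 69
males and 55 females. Meiosis switches haplotypes between adjacent markers
with Haldane probabilities; dams transmit their single Z intact to sons and
the untyped W to daughters, so Z allele counts are always `2 − is_female`.
Because every F1 inherits the wild sire's gamete, the expected autosomal
wild-allele frequency is 0.5 from F1 onward — the quantity the pedigree
tests check, with a tolerance that combines binomial sampling and
drift across the six post-F1 transitions. Planted-marker founder frequency
is effectively 0.5 (fully informative markers). The W carries no phenotyped
content.

The default scaled-down genome is 3 autosomes plus Z, 12 markers per
chromosome (≈16 cM autosomal spacing, 15 cM on Z, matching the sparse
linkage map such a cross needs) and 200 contiguous 1-kb windows per
chromosome — a desk-scale stand-in for the ~1M genome-wide / 82k Z windows
of a full dataset. Window counts are negative binomial with mean
`baseline × (1 + β_sex · dosage) × sex multipliers × batch shift` and
variance `μ + dispersion·μ²` (`dispersion = 0` gives deterministic
noise-free counts); the expected baseline count per window is
`mean_coverage × window_size / read_length` (≈25 reads at 3.4× coverage and
136-bp reads). Baseline Z windows carry a male:female dose ratio of 1.7,
the Z-wide average such data show; MHM blocks multiply male means (3.3-fold
in the bundled examples); per-sex QTL slopes are
`β ± δ/2` for additive effect β and sex-interaction δ. Two batches with a
small multiplicative shift exercise the covariate code paths.

Two noise scales matter. `dispersion` (default 0.3) is count-level
overdispersion. `indiv_sd` (default 0.4) is a multiplicative log-normal
term per window and individual representing biological between-individual
variation; without it the baseline 1.7× Z dose ratio is detected so crisply
at n = 124 that the entire Z would qualify as one MHM run, unlike real
data, where the average per-window sex difference is far from significant.
Both values were fixed once as realistic levels for MeDIP-type data.

Expression is log-normal per probeset (log2 baseline ~N(8,1), residual SD
0.3) with planted eQTL, optional coupling to a methylation window in either
causal direction (expression-to-methylation couplings are injected on the
normalized methylation scale after generation), and optional male
suppression of block-adjacent genes. `simulate_causal_triple()` draws
$(G,E,M)$ directly from the three anchored causal structures for orientation
tests.

What the generator does **not** emulate: read-level sequence artefacts,
MeDIP enrichment bias and CpG-density effects, linkage disequilibrium
beyond the pedigree itself, genuine missing genotypes, population
substructure, and the heavy-tailed outliers of real arrays. Passing tests
therefore demonstrate correctness of the algorithms under the stated
generative model, not robustness to every artefact of real data.

## Problem sizes and numerical choices

The test suite and acceptance script run at deliberate desk scale: studies
of 124 individuals on 2–3 autosomes plus Z with 20–200 windows per
chromosome; 50 seeded replicates for recovery and flag-rate estimates; a
2,000-window null for scanner calibration; 100 random fixtures for the
least-squares equivalence check; permutation runs of 40–200 permutations
over a handful of phenotypes. These sizes were chosen so each property is
measured with useful precision while the whole suite stays interactive.
In the simulation studies the sex-interaction analyses scan `log1p` of the
normalized values: the generative model is multiplicative, so the log scale
makes per-sex allelic effects additive and keeps the 1-LOD interaction rule
calibrated under heteroscedastic count noise.
Numerical guards: residual sums of squares are floored at `1e-300` before
the log-ratio; dosage columns with residual variance below `1e-10` explain
nothing; the SEM fitter returns a large discrepancy for non-positive-definite
candidate covariances; p-value comparisons in block and classification
criteria are strict inequalities, and interval boundaries (cis margin,
overlap endpoints, gene flanks) are closed exactly as stated above.

## Known limitations

- The Wilcoxon normal approximation at n = 124 differs from the exact
  distribution in the far tail, where the MHM p-threshold lives; this
  mirrors common practice but means extreme p-values are approximations.
- The SEM models treat genotype dosage as Gaussian; with three genotype
  classes this is the usual NEO-style approximation, not a categorical
  likelihood.
- Support intervals are 1.5-LOD drops, not calibrated confidence intervals;
  their bp bounds depend on marker density.
- Hotspot merging is defined for consecutive-marker groups only; hotspots
  spread over non-adjacent markers stay separate.
- The generator's normalization couples windows through the per-individual
  total; with very few windows a strong planted hotspot measurably
  attenuates its own per-window effects, which is why simulation tests use
  enough background windows to keep that weight small.
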