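---
title: "Methods: mapping the genetics of DNA replication timing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping the genetics of DNA replication timing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rtqtl)
```

## The measurement model

In an unsynchronised population of proliferating cells, a fraction `s` of
cells is in S phase. A locus replicated in fraction `f` of those S-phase
cells has expected copy number

```
E[CN] = 2 (1 - s) + s (1 + f),      f in [0, 1],
```

so early loci (large `f`) sit a fraction of a copy above late loci.
Windowed read depth from standard whole-genome sequencing of such a
population therefore carries a replication-timing signal on the order of
`s` copies peak-to-trough, against Poisson counting noise. The pipeline's
first half turns this weak signal into per-sample timing profiles; the
second half treats the profile as a quantitative trait and maps its
genetic determinants.

## Profile inference and its thresholds

Filtering happens in two passes with copy-number thresholds that are
package defaults exposed in `filter_thresholds()`:

* **Global pass** (`filter_windows_global()`): windows overlapping assembly
  gaps or known SVs are removed; the *common copy number* is the median
  over windows of each window's across-sample median; windows whose median
  deviates from it by more than 0.4 copies, or whose 25th/75th percentile
  deviates by more than 0.4 copies, are removed. The quartile criterion
  catches windows where a subset of samples misbehaves without moving the
  median.
* **Per-sample pass** (`filter_points_per_sample()`): individual data
  points at least 0.6 copies from the common value (absolute outliers) or
  0.25 copies from the window's across-sample median (relative outliers)
  are masked, as are points in sample-specific CNV intervals. Masked raw
  values are retained in `removed_values`: the rtQTL artifact filter later
  re-tests exactly the data the filters took out.

Profiles are then Z-normalised per sample (mean 0, SD 1 over unmasked
autosomal points) and smoothed with a cubic smoothing spline
(`stats::smooth.spline`), fitted per contiguous segment. Gaps shorter than
300 kb are bridged; longer gaps split the profile; segments spanning less
than 300 kb are dropped because they are dominated by edge effects.

**Choosing the smoothing parameter.** `spar` trades noise suppression
against peak flattening. We calibrated the default (`spar = 0.5`) on the
default synthetic cohort by maximising the per-sample correlation between
the smoothed profile and the known generating curve (about 0.98 at the
default; the correlation with the filtered-raw data is then about 0.7,
reflecting the raw data's Poisson noise share at 30x-equivalent depth).
We deliberately did not push smoothing further: beyond `spar ~ 0.6` the
genome-wide variance collapses faster than local genetic effects, which
*inflates* recovered effect sizes past their true values while
truth-correlation falls — an instructive failure mode for any smoother
calibrated only against itself.

`pc_correct()` removes technical structure as principal components of the
deviation from the cohort-mean profile (the shared timing programme itself
is not a removable "component"). By default a component is flagged
technical when it explains more than 1% of variance and its sample
loadings correlate with no genotype PC (|r| < 0.2): remove batch
structure, keep genetic structure.

## Peaks and timing-variant regions

Peaks are per-sample local maxima (strictly greater than both neighbours;
plateaus take the leftmost window) pooled across the cohort and clustered
by single-linkage with a 200 kb cutoff — for points on a line this equals
splitting sorted positions at gaps above the cutoff, which is what
`call_peak_clusters()` does (and what its test verifies against
`hclust`). A sample contributing several peaks to one cluster keeps only
the one nearest the cluster center; clusters supported by at most 10% of
samples are dropped. Valleys (replication termini) use the same machinery
on the negated profile.

Variant regions start from local maxima of the smoothed across-sample SD
track exceeding the genome-wide mean SD, are confirmed by pairwise Welch
t-tests on filtered-raw values in a 500 kb window (Bonferroni over sample
pairs x candidates), extended in 200 kb windows sliding 100 kb until fewer
than 0.1% of pairs differ at nominal 0.05 (the nominal threshold is used
for extension; the corrected one only for confirmation), merged when
profiles at their SD peaks correlate above 0.9, else split at the SD
minimum. A region must survive removal of its most extreme 1% of samples,
which operationalises "not driven by a handful of lines".

## Two-step rtQTL mapping

Covariates are the first three genotype PCs plus `k` phenotype PCs of the
filtered-raw data; `select_phenotype_pcs()` picks `k` as the value
maximising the number of significant windows under a reduced permutation
budget. Variants enter mapping only with MAF >= 5%, Hardy-Weinberg
p >= 1e-3, and all three genotype classes observed.

**Step 1, window-level.** For each window, all variants within 1 Mb of its
center are tested by linear association on covariate-residualised data
(the per-variant p-value is the exact two-sided t-test of the simple
regression). The window-level p-value asks how often a permutation of the
residualised phenotype produces an equally small minimum p-value; a beta
distribution fitted to the permutation null (method of moments, refined by
maximum likelihood near significance, with a pseudocount-empirical
fallback) extrapolates beyond the permutation count. Permutations run in
chunks with early stopping once 100 exceedances accumulate — unbiased for
borderline windows, cheap for hopeless ones — and each window's stream is
seeded from its window id, so results are reproducible window by window.
Windows pass at Benjamini-Hochberg FDR 0.10 (0.05 supported via the `fdr`
argument); BH is used instead of a pi0-estimating q-value because it is
deterministic at cohort scale.

**Step 2, variant-level.** Within a significant window, every permutation
variant passing a candidate threshold `p_t` is a false positive, so
`FDR(p_t) = mean permutation count passing p_t / observed count passing
p_t`; `variant_threshold()` takes the largest observed p-value with
estimated FDR at most 0.10, from 500 permutations.

**Signals.** Significant variants are peeled greedily: lowest p becomes a
tag, everything in LD (cohort-dosage r-squared >= 0.2) joins its signal,
repeat — so each significant variant belongs to exactly one signal.
Signals need at least 10 members and tag p < 1e-3. Signals found in
different windows consolidate when tags are in LD, windows correlate
(R-squared >= 0.1) and lie within 2 Mb; each consolidated signal is then
re-scanned conditionally on its tag, and a member significant after
Bonferroni seeds a split (members follow whichever tag they are in
stronger LD with). The member-count rule is enforced at identification,
not re-imposed on split parts. The associated region extends from the
strongest window while tag association stays at p <= 0.05.

**Artifact filter.** An unfiltered one-to-two-window CNV in LD with local
SNPs mimics an rtQTL. The filter re-tests the tag against (a) the
filtered-raw data in the region, (b) the smoothed data, and (c) the
removed data within 1 Mb: at least five raw windows must associate at
p < 0.05; the raw minimum p must not undercut the smoothed minimum by more
than one order of magnitude (two/four orders allowed for top p <= 5e-6 /
5e-8, since p-value fluctuations scale with association strength); the
removed-data minimum must likewise not undercut the raw minimum, with at
most two (three for top p <= 5e-8) removed windows beating it; and the raw
minimum must be below 0.01 with a region longer than one window.

Calibration is monitored with the genomic inflation factor
`lambda = median(observed chi-squared) / qchisq(0.5, 1)` (the null median
0.4549 is computed analytically, never hard-coded).

## Multi-rtQTL architecture

Signals whose strongest loci correlate (R-squared >= 0.2) within 2 Mb form
candidate multi-rtQTL regions; each member must add explanatory power by a
nested-model F-test at p < 0.05 (LD between tags does not by itself block
membership — only failing the F-test does). Pooled additivity regresses
focal-locus timing on the count of early-replicating alleles;
`scale = "relative"` Z-scores each locus across samples (the pooled-figure
convention), while `scale = "profile"` re-standardises each sample's full
profile first, so the slope is in the same per-sample Z units in which
effects are defined — the re-standardisation matters because smoothing
leaves profiles shrunk by their residual-noise share.

The additive-vs-synergistic test fits a null line in dosage 0..4 against
an alternative where the dosage values of the 0- and 4-allele groups are
free parameters, Gaussian likelihood with the variance profiled out;
`-2 log LR` is referred to chi-squared with 2 df (the alternative adds the
two group-level parameters). Pairwise interactions use `-1/0/1` genotype
coding with Bonferroni over tested pairs, after pruning windows at r > 0.5
and variants at r-squared > 0.5. Spatial proximity of primary-secondary
pairs is tested against 100 permutations that preserve each pair's genomic
distance while shifting both loci by 1-2 Mb; significance is a one-sided
Z-test with a Shapiro-Wilk check of the permutation medians.

## Chromatin analyses

Enrichment nulls come from matched control variants: at least 2 Mb from
the real tag, MAF within 0.05, distances to the nearest initiation site
(peak-cluster center) and terminus (valley) within 50 kb, cohort-mean
timing within 0.5 Z, and at least as many LD partners. rtQTLs with fewer
than 200 matched tags are excluded from denominators. Each permutation
replaces every rtQTL with a random matched tag plus its LD partners at the
real signal's cardinality; the one-tailed binomial parameter is the mean
permutation overlap fraction (100 permutations by default).

The combination search tests features at individual rtQTL SNPs against
control SNPs by Fisher's exact test (two-sided at level 1 so depletion is
reportable; one-sided enrichment at deeper levels, which test directional
improvement), BH-corrected at 5% FDR within each level; level `m + 1`
restricts both SNP sets to carriers of a level-`m` combination and stops
when nothing passes. Hyperacetylated trimethylation regions keep five-mark
co-occurrence sites overlapping at least 11 distinct variable acetylation
marks and merge survivors within 10 kb.

Allelic covariation compares, across rtQTL sites, the fraction of
early-genotype lines carrying a mark near the site with a two-tailed
binomial whose parameter is `p_late * (p_perm_early / p_perm_late)` — the
late fraction rescaled by the same ratio observed in ten permutations with
matched SNPs and randomly assigned early alleles; with so few permutations
the ratio is clipped to [0.01, 100]. TF motif association weights each
rtQTL by the motif-score difference between its early and late allele (one
SNP per rtQTL, the lowest-p member in the motif table), compares weighted
early-higher/late-higher totals with a permutation baseline in a 2x2
chi-squared test without continuity correction, BH at 10% FDR, and
excludes TFs overlapping fewer than 15 rtQTLs.

## Prediction

Distances from predicted regions to peak boundaries are zero on overlap,
else the bp gap; fractional distance divides by half the span between the
two flanking peak centers (0 at a peak, 1 midway; single flanking span at
chromosome ends) — this definition is an interpretation fixed by the
package, stated here because "fractional distance" is not otherwise
standardised. Baselines shift regions by 1-2 Mb in either direction,
reflecting at chromosome ends. PPV is the fraction of regions within the
cutoff (default 10 kb) of a peak; sensitivity the fraction of peaks within
the cutoff of a region. ROC curves sample 1000 windows inside peak
boundaries as positives and 1000 windows farther than 750 kb from any peak
center as negatives (without replacement, shrinking with a warning when
eligible windows run short), predict "peak" within a cutoff distance of a
region, and integrate the (0,0)-(1,1)-anchored curve by trapezoid.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure the analysis
assumes. The baseline timing curve is a sinusoid with 1 Mb peak spacing
and `sqrt(2)` amplitude (unit genome-wide variance, so planted effects are
genuine Z units); each planted rtQTL shifts timing by `effect_size` per
early (alternative) allele with a linear taper over a 400 kb half-width —
about the span over which real timing effects decay. Timing maps to
replicated fraction through a logistic with scale 3, chosen to keep the
map near-linear over the observed Z range (a mid-S-phase response) while
staying monotone and bounded; the quantitative S-phase-to-dynamic-range
map is not fixed by biology, and this choice is flagged as a modelling
decision. Counts are Poisson around 3000 reads per window (30x-equivalent
coverage at 10 kb) at S-phase fraction 0.45 (mid-range for cultured
pluripotent lines), with an optional extra Gaussian copy-number noise
(default 0.02) standing in for residual GC/mapping wobble. Genotypes live
in 100 kb LD blocks as haplotype copying chains with a 5% per-variant
redraw rate, giving r-squared decay within blocks and independence across
them. CNVs and per-sample histone tracks (background Poisson intervals,
cohort-level peak placement, genotype-conditional presence with
configurable odds at planted rtQTLs) complete the picture. One global
seed drives every substream.

What the generator does *not* emulate — GC waves, mappability structure,
population stratification beyond LD blocks, imputation error, real
chromatin geography — bounds what passing tests show: they demonstrate the
machinery is correct and calibrated under the stated model, not that the
defaults are optimal for any particular real dataset.

## Problem sizes and numerical choices

The bundled checks run null-FDR control on twenty cohorts of 100 samples,
2,000 windows and ~5,000 variants; recovery on a cohort of 150 samples and
6,000 windows with twenty planted rtQTLs (effect 0.6 Z per allele, MAF
0.3); LRT calibration on 1,000 additive-truth regions; and prediction
calibration on a 500 Mb grid with ~750 peaks — sizes chosen so the full
suite completes comfortably on a single CPU while leaving the binomial
noise on each checked fraction well inside its acceptance band.

The prediction-calibration landscape deserves a note. A shifted-region
null is only centred at AUC 0.5 when a 1-2 Mb shift actually decorrelates
regions from the peak process: with periodic or multi-Mb peak spacing, the
windows beyond 750 kb of any peak live in locally peak-poor
neighbourhoods that shifted (still peak-anchored) regions continue to
track, and the null AUC is structurally biased by 0.05-0.10 in either
direction depending on the geography. The calibration landscape therefore
draws initiation sites as a memoryless (Poisson) process with ~0.5 Mb
mean spacing — matching the sub-Mb spacing of real initiation zones —
places the non-hit regions uniformly, and excludes 2.5 Mb chromosome-end
margins from window sampling (end deserts see regions on one side only).
Under that geography the shifted null was verified to sit at AUC ~0.51
across independently drawn landscapes.

Degenerate inputs are handled explicitly: zero-variance samples error in
normalisation; windows with no cis variants are skipped with a log entry;
collinear interaction pairs are skipped; degenerate beta fits fall back to
the pseudocount empirical p; constant contact matrices give Z = 0,
p = 0.5; permutation-ratio divisions are clipped. Ties in tag selection
break to the smaller genomic coordinate; "orders of magnitude"
comparisons use strict log10 inequalities.

## Known limitations

Cohort-dosage LD is a noisy stand-in for reference-panel LD at small n;
the conditional split runs one round rather than a full stepwise
conditional analysis; sex chromosomes are out of contract (autosome-only);
and the spline penalty, although calibrated, remains the single most
influential tunable — users with materially different coverage or S-phase
fractions should re-run the calibration sweep described above.
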