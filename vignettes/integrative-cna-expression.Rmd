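---
title: "Integrative copy-number and expression analysis of colorectal cancer subtypes: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative copy-number and expression analysis of colorectal cancer subtypes: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnacms)
```

## Scope and model

`cnacms` implements an integrative analysis of somatic DNA copy-number
aberrations (CNAs) and bulk gene expression in microsatellite-stable (MSS)
colorectal cancer, organized around the consensus molecular subtypes (CMS).
The pipeline consumes *segmented* copy-number profiles — segmentation itself
(PCF, ASCAT) is out of scope — in two forms:

* **relative segments**: per-sample mean log-ratios of piecewise-constant
  fitted profiles, used for gain/loss calling and dosage integration;
* **allele-specific segments**: integer allele copies (nA, nB) with total
  nAB, used for amplification calling, LOH, and ploidy.

Chromosomes X and Y are excluded throughout. Coordinates are 0-based
half-open internally; segment TSVs are 1-based inclusive on disk, BED is
native.

## Copy-number core

Relative profiles are median-centered per sample with a base-pair-weighted
median (the smallest value whose cumulative weight reaches half the total —
deterministic, and exact on integer-valued profiles). States are called at
**±0.15** with *inclusive* thresholds; the threshold convention is not
fully determined by the usual description of such pipelines, so the
inclusive choice is fixed here and tested at the boundary.

Genes are assigned values from the segments they overlap
(`GenomicRanges::findOverlaps`), resolving breakpoint conflicts in four
rules: all-gain/all-loss keeps the most extreme value; all-neutral takes
the median segment value; neutral-plus-one-direction keeps the most extreme
aberrant value; gain-plus-loss is missing. Genes without any overlapping
segment are missing with a distinct `no_coverage` reason. A per-base
brute-force oracle checks the mapping on 1,000 random configurations.

Amplifications are defined on allele-specific data as total copies at least
**5 above the sample-wise genome-wide median** (base-pair-weighted median of
nAB). Peaks are maximal runs of *literally adjacent* amplified segments —
segmentations are genome-covering, so no gap tolerance is needed. A peak is
**high-level** at ≥ 15 additional copies and **focal** at ≤ 50 covered
genes ("≤" chosen over the sometimes-seen "< 50"; with the scaled genome
the boundary is rarely hit). Ploidy is the length-weighted mean of nAB,
dichotomized at 2.2n. LOH requires exactly one zero allele; homozygous
deletions are not LOH.

## In cis integration

Genes with expression variance < 0.1 are excluded. For each remaining gene,
expression is compared between copy-number aberrant and neutral samples
(two-sided Wilcoxon rank-sum; exact enumeration when both groups have ≤ 10
samples without ties, otherwise normal approximation with tie and
continuity corrections), and correlated with the *continuous* relative
copy-number value by Spearman's rho (the continuous value retains more
dosage information than the 3-level state; p from the t approximation).
A gene is **in cis** when the Wilcoxon FDR and the Spearman FDR are both
below 0.05, rho is positive, and the median shift is in the tested
direction. FDR families are per direction (gain/up; loss/down), computed
over the evaluable genes only (both groups at or above the minimum size:
10 genome-wide, 3 inside resampling iterations).

Amplification–expression concordance uses two rules: (i) a peak passes
when any covered gene's expression in the amplified sample is *strictly*
above Q3 + 1.5·IQR of the cohort (type-7 quantiles); (ii) a recurrently
amplified gene passes when at least 50% of its k carriers rank in the top
`max(5, ceiling(1.5k))` samples by expression (ceiling keeps the window
inclusive, matching the "top five when k < 5" convention; ties are broken
by stable sample order, which matters only on exactly tied expression
values).

## Differential expression and subtype enrichment

Subtype contrasts (one CMS vs the remaining classified tumors; unclassified
samples excluded) use an empirical-Bayes moderated t implemented in the
package: per-gene pooled variances are shrunk toward a prior estimated by
moment matching on the log sample variances, and the statistic is referred
to a t distribution with prior-plus-residual degrees of freedom. The
estimator agrees numerically with the standard limma fit on fixtures, and
collapses to the ordinary pooled t when the prior weight is zero (also the
fallback below 10 genes). "Upregulated" requires FDR < 0.05 **and** log2
fold change strictly above `log2(1.2)` — the fold-change cutoff is applied
on the log2 scale.

The **overlap fraction** of a subtype is the share of its upregulated genes
that are also in the in cis gain set. Three resampling variants control for
subtype sample sizes (20 tumors per subtype per iteration, in cis recomputed
on the pooled 40 with per-iteration FDR): variant i recomputes differential
expression per iteration, variant ii reuses the original all-sample
upregulated lists, and variant iii draws 250 genes from those lists.
Gene-list resampling (250 + 250) additionally controls for unequal list
lengths. Per-iteration sub-seeds are derived deterministically from the
root seed, so distributions are reproducible and independent of iteration
order. `prop_a_greater` splits ties evenly; without tie-splitting an
all-null comparison would be driven entirely by zero-zero ties.

Microenvironment depletion removes genes upregulated in the fibroblast,
endothelial or leukocyte compartments of a sorted-cell reference (one-vs-
rest contrasts at the same thresholds); epithelial-specific genes are
retained. Compartment enrichment of the in cis set uses 2×2 Fisher tests
(two-sided, point-probability method) over the variance-filtered universe.

## Survival

Five-year overall survival among stage I–III MSS patients: events after
5 years are censored at 5. Exposure is carriage of a recurrent focal
high-level amplification (≥ 5 additional copies as a secondary grouping).
Kaplan–Meier, log-rank, and Cox proportional hazards with Efron tie
handling; multivariable models include age dichotomized at the analysis
cohort's median, gender, localization, and stage as a factor with stage I
as reference (separate levels rather than a linear score, the less
restrictive of the two plausible codings).

## The synthetic cohort generator

The generator produces the joint structure the analysis assumes, with
recorded truth; defaults were fixed once to a scaled version of the study
design and are not tuned per test:

* 150 tumors, 20% microsatellite-instable (near-flat genomes, no
  amplifications); CMS proportions ≈ 7/42/15/23% with the remainder
  unclassified.
* A 22-autosome genome of 10 Mb chromosomes carrying ~2,000 evenly spaced
  genes — segment/gene topology is preserved while keeping runtimes in
  seconds.
* Ploidy 2n or 4n (35% tetraploid); Poisson(3) breakpoints per chromosome;
  background per-segment gain/loss probability 0.10; each subtype owns
  "program chromosomes" (e.g. 8/13/20 for CMS2) gained with probability
  0.7 in that subtype — mirroring the known gain landscape.
* Tumor purity ~ Normal around subtype means (0.70 CMS2 vs 0.45 CMS4 —
  CMS4's strong stromal infiltration), truncated to [0.2, 0.95].
* Each subtype has a 250-gene expression program of which a configurable
  fraction θ (default 0.5 for CMS2, ≈0.05–0.1 elsewhere, matching the
  reported 50% vs 4–6% contrast) is **dosage-driven**: those genes sit on
  the subtype's program chromosomes and respond to copy number with
  1 log2 unit per additional copy (saturating at +6/−2 copies); the
  remaining program genes sit on neutral chromosomes with a fixed +1 log2
  intrinsic shift, so their expression is uncorrelated with copy number by
  construction.
* Focal amplifications: Poisson(0.8) per MSS sample, 1–10 genes wide,
  additional copies uniform on 5–100; all covered genes respond to dosage
  in the carrier. Bulk expression mixes malignant and stromal profiles on
  the intensity scale weighted by purity, then adds N(0, 0.3²) log2 noise.
  The stromal profile carries a 180-gene microenvironment program (+2 log2,
  split across fibroblast/endothelial/leukocyte) that the sorted
  compartment reference shares.
* Survival: exponential times (0.06 events/year baseline), hazard ×3 for
  carriers of an injected high-level focal amplification, administrative
  censoring at 8 years (before the 5-year analysis censoring).

What the generator does **not** emulate: probe-level noise and waviness,
subclonal copy-number states, whole-genome doubling as a process,
correlated gene-gene expression modules, and realistic survival covariate
effects (age/gender/localization/stage are independent of outcome). Tests
passing on this generator therefore certify the *inference machinery* —
calibration, recovery of planted structure, determinism — not performance
on real arrays.

## Numerical and design choices

* Weighted medians use base-pair lengths (probe counts are not part of the
  data model).
* The Wilson interval is computed without continuity correction — this
  reproduces published frequency-table intervals exactly at 1-decimal
  rounding (e.g. 3/203 → [0.5%, 4.3%]).
* Spearman p-values use `t = rho·sqrt((n−2)/(1−rho²))`; |rho| = 1 is
  clamped at 1 − 1e−12 to keep the statistic finite.
* Fisher's two-sided p sums hypergeometric point masses ≤ the observed
  mass, matching the R default and published p-values.
* BH adjustment is the standard step-up; note it is *not* idempotent in
  general (re-adjusting adjusted values can change them), so no such
  invariant is relied on.
* Degenerate inputs are explicit: empty groups are "not evaluable" rather
  than p = 1; zero-variance genes carry p = 1 in the moderated t; empty
  upregulated sets give an undefined (flagged) overlap fraction.

## Problem sizes

The shipped analysis and tests run the default 150-tumor, 2,000-gene
cohort; recovery of the dosage-driven fraction is checked on 80-tumor
cohorts at θ = 0.1 and 0.5; resampling checks use 200 iterations; survival
calibration uses 100 replicates at n = 400–500. These sizes were chosen so
that each stage's statistical behaviour is clearly resolved while the full
suite runs in minutes on one CPU.

## Known limitations

* The amplification "additional copies" scale is relative to the
  genome-wide median, so near-triploid genomes shift the scale; the
  generator only produces 2n/4n genomes where the median equals the
  ploidy.
* The in cis test conditions on called states; borderline segments
  (|value| ≈ 0.15) flip groups under small centering changes.
* Variant i resampling recomputes differential expression on 20 vs 20
  tumors, which is underpowered relative to the full cohort — its
  distributions are wider than variants ii/iii by design.
* With heavy ties in expression, top-rank membership depends on the
  documented stable tie-break.
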