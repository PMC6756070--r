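# cnacms

Integrative DNA copy-number and gene-expression analysis of
microsatellite-stable (MSS) colorectal cancer, organized around the
consensus molecular subtypes (CMS).

About 80% of colorectal cancers show chromosomal instability, but most
copy-number aberrations (CNAs) are passengers: the question this package
addresses is *which* CNAs actually move gene expression, and whether the
expression programs that define the CMS subtypes are copy-number driven.
It is written for cancer-genomics analysts who have segmented copy-number
profiles (relative log-ratios plus allele-specific integer copies) and a
matched bulk expression matrix, and want a tested, reproducible
re-implementation of this class of integrative analysis.

## What it computes

* **Gene-level CNA calls** from segmented profiles: per-sample median
  centering (base-pair-weighted), gain/loss at ±0.15, breakpoint-conflict
  resolution (most-extreme / median / aberrant-wins / conflict-missing),
  genome fraction aberrant, LOH (exactly one zero allele), ploidy with the
  2.2n dichotomy.
* **Amplification peaks**: total copies ≥ 5 above the sample-wise
  genome-wide median, maximal runs of adjacent amplified segments,
  high-level at ≥ 15 additional copies, focal at ≤ 50 genes; recurrent
  amplified genes with Wilson 95% CIs.
* **In cis dosage testing**: per gene, two-sided Wilcoxon of expression in
  aberrant vs neutral tumors plus Spearman correlation with the continuous
  copy-number value; a gene is *in cis* when both FDRs < 0.05 and rho > 0:

  gain/up: FDR(p_Wilcoxon) < 0.05 ∧ ρ_Spearman > 0 ∧ FDR(p_ρ) < 0.05

* **CMS enrichment**: per-subtype upregulated genes (moderated t,
  FDR < 0.05, fold change > 1.2), overlap with the in cis gain set,
  subtype resampling (20 tumors per subtype × 1000 iterations, three
  variants) and 250-gene list resampling, microenvironment depletion
  against a sorted-compartment reference, compartment Fisher enrichment.
* **Survival**: 5-year overall survival of amplification carriers among
  stage I–III MSS patients — Kaplan–Meier, log-rank, uni-/multivariable
  Cox (Efron ties).
* **A synthetic cohort generator** emulating all of the above with ground
  truth (CMS-dependent CNA burden, purity/stromal admixture, dosage
  effects, injected focal amplifications, survival hazards) for recovery
  testing.

## Worked example

```r
library(cnacms)

cohort  <- simulate_cohort(sim_config(seed = 7))
compref <- simulate_compartment_reference(cohort)
bundle  <- run_pipeline(cohort, pipeline_config(seed = 7, resample_iters = 50),
                        compartment_ref = compref)

bundle$overlaps
#>   subtype n_upregulated n_overlap overlap_fraction
#> 1    CMS1           253        12       0.04743083
#> 2    CMS2           256       125       0.48828125
#> 3    CMS3           249        20       0.08032129
#> 4    CMS4           413        20       0.04842615

bundle$resample$CMS2_vs_CMS4$prop_a_greater
#> [1] 1

bundle$survival$cox_multivariable[1, ]
#>        term       hr ci_lower ci_upper           p         model
#> 1 amplified 2.210586 1.222503 3.997285 0.008672739 multivariable
```

Reading: about half of CMS2-upregulated genes are driven by copy-number
gain (the generator's configured dosage-driven fraction for CMS2 is 0.5),
versus ~5–8% in the other subtypes; CMS2's overlap fraction exceeds CMS4's
in every resampling iteration; and carriers of recurrent focal high-level
amplifications have roughly doubled hazard of death within five years
(truth: hazard ratio 3, attenuated by carrier misclassification in the
detected exposure groups).

The same analysis, staged over files, lives in `analysis/01_simulate.R`
… `analysis/05_survival.R`; each stage reads `results/cohort/` and writes
its tables under `results/`.

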