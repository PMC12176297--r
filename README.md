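# xiquant

Quantitative pipelines for studying how the SAF-A/HNRNPU SAP domain
supports X-chromosome inactivation and nuclear protein dynamics — the
kind of multi-assay phenotyping done in degron cell lines where the
endogenous protein is rapidly destroyed and GFP-tagged mutants are
expressed in its place. The package re-implements, as reusable and tested
R code, the five bespoke quantitative procedures such a study needs, and
ships seeded synthetic-data generators so that every pipeline can be
validated against known ground truth without the original microscopes or
sequencers.

## What it computes

**3D XIST RNA foci counting.** XIST RNA is present at ~50 copies per
nucleus but appears as a "cloud" over the inactive X (Xi) at confocal
resolution; a localization defect shows up as an increased number of
*resolvable* RNA foci per nucleus. The pipeline follows the batch
ImageJ-style recipe: per-slice Gaussian blur + Otsu threshold + fill-holes
on the DAPI channel, 3D connected components, exclusion of nuclei touching
the XY border; one global 3D Otsu on the RNA-FISH channel for particles;
particle-to-nucleus assignment by maximal voxel overlap; anisotropy-aware
distances; per-nucleus summaries (`segment_nuclei()`, `segment_foci()`,
`assign_foci()`, `pairwise_distances()`, `summarize_nuclei()`,
`batch_process()`).

**FRAP kinetics.** Traces are normalized to the pre-bleach mean and fit
with a single-exponential recovery
F(t) = F∞ − (F∞ − F0)·e^(−kt), reporting t½ = ln2/k and the immobile
fraction (1 − F∞)/(1 − F0) per cell and per condition
(`normalize_trace()`, `fit_recovery()`, `summarize_condition()`).

**Allele-specific (Xi vs Xa) analysis.** DNA-validated SNP filtering
(drop zero-count SNPs, then SNPs whose bias a/(a+b) deviates >1 SD from
the mean), gene-level aggregation, strict count filters (>10 for
expression, IgG-subtracted ≥0 per allele and >5 total for chromatin
profiling), replicate-averaged a:b ratios, and a reactivation screen
using per-gene conditional exact tests with BH correction
(`filter_snps()`, `aggregate_to_genes()`, `filter_genes()`,
`ab_ratios()`, `subtract_igg()`, `reactivation_screen()`).

**K-mer enrichment.** Overlapping k-mer counts (k = 5–8) in experimental
vs control sequence sets and a log2 pseudocounted frequency-ratio
enrichment score (`count_kmers()`, `enrichment_table()`).

**Replicate statistics.** Superplot summaries (replicate means, grand
mean, SD of replicate means), one-way ANOVA with Tukey HSD and the
study's literal Bonferroni-on-Tukey combination, percent-positive scoring
with replicate-level Welch t-tests, and fold changes with bootstrap CIs
(`superplot_summary()`, `anova_tukey()`, `percent_positive()`,
`fold_change()`).

**Synthetic data.** `sim_image_population()` (two-channel 3D stacks:
ellipsoidal nuclei, PSF-blurred puncta, Poisson + read noise, 8-bit
digitization, with per-nucleus ground truth including the
resolvable-focus count under single-linkage merging at 2·σ_lateral),
`sim_frap_traces()`, `sim_allele_tables()` /
`sim_reactivation_experiment()`, and `sim_sequences()`. Shipped presets
`foci_presets("wt")` and `foci_presets("depleted")` differ only in the
dispersed fraction of puncta; the depleted value is calibrated so the
expected ground-truth foci count doubles.

## Worked example

Simulate 25 FRAP movies at the study's acquisition protocol (10 pre-bleach
frames, 65 ms interval, 30 s post-bleach) for a wild-type-like condition
(t½ = 2.58 s, immobile fraction 18%) and a faster SAP-mutant-like
condition, and fit each cell:

```r
library(xiquant)
wt  <- sim_frap_traces(frap_sim_params(t_half = 2.58, immobile_fraction = 0.18), 25, seed = 501)
mut <- sim_frap_traces(frap_sim_params(t_half = 2.0,  immobile_fraction = 0.12), 25, seed = 502)
fits <- lapply(c(wt, mut), fit_recovery)
summarize_condition(fits, rep(c("wt", "sap_mutant"), each = 25))$table
```

```
  condition  n mean_t_half  sd_t_half mean_immobile sd_immobile
         wt 25    2.581572 0.04382682     0.1823131 0.006616821
 sap_mutant 25    2.002568 0.02590453     0.1187037 0.005994308
```

The fitted condition means recover the generator kinetics: mean t½ within
0.1% of 2.58 s and a mean immobile fraction of 18.2% for the wild-type
ensemble, with the mutant condition clearly faster — the pattern the FRAP
assay is designed to resolve.

The numbered drivers under `analysis/` run the other pipelines end to end
and write their tables under `results/`:

* `analysis/01_foci_pipeline.R` — simulates both presets (30 nuclei each
  at this driver's scale), counts foci per nucleus through the full
  segmentation pipeline (wt: mean 3.33 foci/nucleus vs ground truth 3.40;
  depleted: 7.33 vs 7.63), and reports the fold change, 2.20 (95% CI
  1.80–2.70, bracketing this sample's ground-truth ratio 2.25), with a
  one-way ANOVA of F = 57.7, p = 2.9e-10.
* `analysis/03_allelic.R` — on synthetic tables, the SNP filter flags
  exactly the 20 planted biased SNPs out of 1062; class-level mean
  proportions come out at 0.499 (autosomes), 0.949 (X-inactivated) and
  0.495 (escape); the reactivation screen finds all 30 planted genes at
  FDR 0.05 with an empirical FDR of 0.06.
* `analysis/04_kmer.R` — a hexamer planted in half of 1000 sequences
  ranks first of 4096 (score 4.38), and its sub/super-k-mers rank first
  for k = 5, 7, 8.

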