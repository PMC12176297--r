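---
title: "Models, assumptions and numerical choices in xiquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, assumptions and numerical choices in xiquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

xiquant bundles the quantitative procedures of a degron-based study of the
SAF-A/HNRNPU SAP domain: counting resolvable XIST RNA foci in 3D confocal
stacks, FRAP recovery kinetics, allele-specific (Xi vs Xa) count analysis,
k-mer enrichment scoring, and replicate-aware statistics. Because the
original images, movies and sequencing libraries are not shipped, every
pipeline is validated against seeded synthetic data with known ground
truth. This vignette records the models behind each module, the defaults
and why they were chosen, and the numerical corners a user should know
about.

## 1. The synthetic imaging model

`sim_image_population()` generates two-channel stacks that emulate the
acquisition used for foci counting: 0.2 µm z-steps (the protocol's value)
and a 0.1 µm lateral pitch, a Nyquist-scale choice for a 1.4 NA lens — the
lateral pixel size of the original acquisitions is not recorded, so it is
exposed as a parameter. Nuclei are ellipsoids with semi-axes drawn from
RPE-1-like ranges (defaults: 4.6–5.6 µm lateral, 1.9–2.2 µm axial), placed
fully inside the XY field with at least a voxel of clearance; an optional
deliberately edge-touching nucleus exercises the border-exclusion rule.

Each nucleus receives `n_puncta = 50` RNA puncta, matching the ~50 XIST
copies per nucleus reported for cell-culture models of X inactivation. A
punctum is a point source convolved with an anisotropic Gaussian PSF
(defaults σ~lat~ = 0.15 µm, σ~ax~ = 0.4 µm, roughly confocal at this
wavelength and NA). A fraction `dispersed_fraction` of puncta is uniform
over the nucleus; the rest sit in a "territory" sphere
(`territory_radius`, default 0.1 µm — deliberately sub-resolution, so the
cloud is a single resolvable object) emulating the Xi. Photon noise is
Poisson on the ideal signal plus a constant background (default 4 counts),
read noise is additive Gaussian (SD 2), and intensities are digitized to
8-bit range (`max_intensity = 255`).

Two features of this model are deliberate and worth spelling out:

* **The cloud saturates the detector.** Fifty RNA molecules inside a
  sub-resolution volume stack their PSFs: the cloud's would-be peak is
  tens of times a single punctum's. Under a global Otsu threshold an
  unclipped cloud dominates the between-class variance and pushes the
  threshold far above single-molecule peaks, so dim dispersed foci would
  never be detected. Real acquisitions behave like the clipped model: gain
  is set so single molecules are visible and the XIST cloud saturates.
  The 8-bit ceiling is therefore part of the acquisition model, not a
  convenience.
* **Ground-truth "resolvable foci"** are defined by single-linkage merging
  of true punctum positions at 2σ~lat~ (0.3 µm), an explicit, testable
  Rayleigh-type criterion. The count is computed by union-find over all
  pairs and is cross-checked in the tests against hierarchical
  single-linkage clustering.

Two presets ship with the package. `"wt"` uses `dispersed_fraction =
0.05`. `"depleted"` uses 0.120, calibrated by a geometry-level Monte Carlo
(12,000 nuclei per candidate value) so that the expected ground-truth
resolvable-foci count is twice the wt preset's (3.5 vs 7.0 per nucleus),
mirroring the reported 2-fold increase in XIST foci on protein depletion.
The calibration uses only punctum geometry, never segmentation output.

## 2. The foci-counting pipeline

`segment_nuclei()` follows the published macro: per-slice Gaussian blur
(σ = 2 px, lateral only), per-slice Otsu threshold, binary fill-holes,
then 3D connected components (26-connectivity by default), removal of
components touching the X or Y border anywhere, and a minimum volume of
500 voxels. Two choices were open and are documented here:

* **Empty-slice guard.** Otsu on a slice containing only background splits
  the noise distribution and floods the slice. A slice's threshold is used
  only if it reaches at least half the global 3D Otsu threshold of the
  blurred DAPI volume (`slice_threshold_frac = 0.5`). The source macro is
  silent on this; without a guard the pipeline is not usable on stacks
  whose z-range extends beyond the nuclei.
* **Edge exclusion is lateral only.** Confocal stacks routinely truncate
  nuclei in z; excluding on the z border would discard most nuclei.

`segment_foci()` applies one global Otsu threshold to the whole 3D FISH
volume (a per-slice switch exists; per-slice thresholding fragments dim
foci), labels components in 3D, and drops components under 2 voxels.
`assign_foci()` uses maximal voxel overlap with ties broken towards the
smaller nucleus label (a centroid-containment mode exists); max-overlap is
robust for foci straddling the nuclear rim. `summarize_nuclei()` reports
per-nucleus counts, total focus volume, and the mean nearest-neighbour
distance, with unassigned foci reported separately so counts always
conserve. `batch_process()` drives the whole pipeline over a manifest,
logging and skipping unreadable images.

**Operating regime.** On the shipped presets the pipeline recovers the
ground truth closely (measured on 100 simulated nuclei per preset: mean
counts within a few percent, fold change within the bootstrap CI of the
ground-truth ratio). Recovery degrades when many puncta are dispersed at
high density with no bright cloud: (i) threshold-based segmentation cannot
separate puncta closer than ~2.8σ laterally or ~3σ axially, while the
ground-truth definition splits at 2σ~lat~, so dense scenes are undercounted
by 15–25%; and (ii) with only dim sparse foci in the histogram, a global
Otsu threshold can collapse into the background mode. Both effects are
properties of single-threshold segmentation, not bugs; passing tests on
the presets therefore demonstrate recovery in the cloud-plus-dispersed
regime the assay was designed for, not on arbitrary scenes. Real images
additionally contain autofluorescence texture, uneven illumination and
optical aberrations that the simulator does not model.

## 3. FRAP kinetics

Traces are normalized by the pre-bleach mean (after optional background
subtraction). Recovery is fit as a single exponential

F(t) = F∞ − (F∞ − F0)·exp(−k·(t − t_bleach)),  t½ = ln 2 / k

with the immobile fraction defined from the fitted plateau as
(1 − F∞)/(1 − F0), clamped to [0, 1]. One component is fit because the
study reports one half-time and one immobile fraction per condition; a
reader wanting two-component kinetics should fit externally. The
initializer is deterministic (F0 from the first post-bleach frame, F∞ from
the last 10% of frames, k from a log-linear fit of the fractional
recovery), refined by Levenberg–Marquardt; non-convergence is flagged,
never silently defaulted. A perfectly flat post-bleach trace short-circuits
to immobile fraction 1. The generator's defaults are the study's protocol
(10 pre-bleach frames, 65 ms interval, 30 s post-bleach — the frame count
follows from duration/interval) and wild-type kinetics (t½ = 2.58 s,
immobile 18%); bleach depth F0 = 0.2 and acquisition noise SD 0.02
(normalized units) are typical values for a small-ROI confocal bleach and
are not stated in the source. Two open points were decided as follows: the
cited normalization protocol is not reproduced in the source text, so
single normalization is the default (double normalization is available by
passing a reference as background); and the immobile fraction uses the
fitted plateau rather than the 30-s endpoint — with t½ ≈ 2.6 s the two
differ by well under 1% at 30 s.

## 4. Allele-specific analysis

The SNP filter is implemented exactly as stated: drop SNPs with a zero
count for either allele in the DNA library, then drop SNPs whose bias
a/(a+b) deviates from the mean by more than one (sample) standard
deviation, both moments computed over the zero-filtered set. Two details
are deliberate: the bias scale (a proportion) is not defined in the
source and is declared here; and the filter is a single pass — the SD
step is not idempotent on continuous data, because truncating the tails
shrinks the SD, so re-running the filter on its own output can remove
more SNPs. Gene filters are strict inequalities as quoted (> 10 total
counts for expression libraries; ≥ 0 per corrected allele and > 5
corrected total after IgG subtraction, with genes absent from the IgG
table treated as zero background). Ratios are reported both as
proportions a/(a+b) and as odds a/b; replicate averaging uses proportions
so that b = 0 genes (infinite odds, flagged) cannot poison means.

The reactivation screen replaces the original negative-binomial framework
with a per-gene conditional exact test on the pooled 2×2 allele-by-
condition table plus Benjamini–Hochberg correction — transparent and
oracle-checkable (the tests enumerate the hypergeometric tail directly);
its gene lists are not expected to match the original tool's numerically.
The log2 fold change is of the a:b odds, with a Haldane–Anscombe 0.5
correction only when a zero count appears.

The allele simulator draws gene totals from a negative binomial (mean
200, dispersion 0.05 per library), splits them multinomially across 3
SNPs per gene, and splits alleles binomially at the class proportion
(autosomes 0.5, X-inactivated 0.95, escape 0.5) — so per-SNP counts within
a gene sum exactly to the emitted total. The DNA validation library uses
depth 1000 per SNP with 20 planted SNPs shifted by ±0.4 in proportion
(~25 binomial SDs, so planted SNPs are essentially always flagged while
unplanted strays are rare). Reactivation is modeled by moving chosen
X-inactivated genes from 0.95 to 0.6 in the perturbed condition.

## 5. K-mer enrichment

Counting is overlapping, single-strand (these are RNA-side motifs), with
windows containing ambiguity codes skipped and reported. The enrichment
score is a declared definition — the source never prints its formula —
namely the log2 ratio of pseudocounted position-normalized frequencies,
with pseudocount 1 over all 4^k k-mers. It is antisymmetric under swapping
the sets, zero for identical sets, and finite for any input. Frequencies
are normalized per position (per window) rather than per sequence; with
equal-length sets the two differ only in the pseudocount's weight.

## 6. Replicate statistics

Superplot summaries reduce per-cell values to replicate means; the grand
mean is the mean of replicate means and is invariant to per-cell n within
a replicate. The omnibus test is a one-way ANOVA on per-cell values (the
source does not say whether cells or replicate means were tested;
per-cell is the default here and replicate means can be passed directly),
followed by Tukey HSD. The source's stated combination — "Tukey's tests
with a Bonferroni correction" — is statistically unusual since Tukey
already controls the family-wise error rate; it is implemented literally
(Tukey-adjusted p times the number of comparisons, capped at 1) and the
plain Tukey p-values are emitted alongside, labeled. Replicate-level
percent-positive comparisons use unpaired two-sided Welch t-tests by
default (the variance assumption is unstated; a pooled option exists).
Fold changes are ratios of means with a seeded nonparametric bootstrap
percentile CI (default 10⁴ resamples).

## 7. Problem sizes and determinism

Every generator takes an explicit seed and is bit-reproducible at a fixed
seed. The analysis drivers under `analysis/` use 30 nuclei per preset, 25
FRAP traces per condition, 354 genes × 2 replicates, and 1000+1000
sequences; the acceptance script uses 100 nuclei per preset (50 stacks of
64×256×256 voxels each, about 4 s per stack on one core) and 25 FRAP
traces. The test suite's oracle checks run 1000 random histograms against
an exhaustive Otsu scan, 50 random 5×5×5 assignment toys against a
per-voxel tally, 20 seeded null screens, and a 20,000-permutation ANOVA
oracle; these sizes were chosen so the whole suite runs in a few minutes
on a laptop core.

## 8. Known limitations

* The PSF is Gaussian, not a physical (Gibson–Lanni) model; no
  depth-dependent aberrations, no uneven illumination, no chromatic
  offsets between channels.
* The noise model is Poisson + Gaussian read noise; no detector gain
  calibration, no dark-current structure.
* The foci pipeline is not a general spot caller: no multi-scale (LoG)
  detection, no deconvolution, and no attempt to reproduce ImageJ's
  filter kernels bit-for-bit.
* The reactivation screen is an exact-test stand-in for the original
  NB-based screen by design; effect-size shrinkage and dispersion
  modeling are out of scope.
* FRAP fitting is reaction-free single-exponential; diffusion-coupled
  recovery or spatial bleach-profile analysis requires other tools.
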