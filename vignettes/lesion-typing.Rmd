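---
title: "Typing T1-hypointense MS lesions: model, phantom and numerical choices"
author: "bhtyper"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Typing T1-hypointense MS lesions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The procedure

`bhtyper` implements a pipeline for typing T1-hypointense multiple
sclerosis lesions from three co-registered sequences (FSPGR, SE, FLAIR)
with a lesion label mask and WM/GM/CSF partial-volume maps per subject:

1. **Intensity standardization.** Each sequence is mapped onto a cohort
   landmark scale: the deciles (10th-90th percentile) of every volume are
   averaged across the cohort, and each volume's own deciles are mapped
   piecewise-linearly onto those standard landmarks, with linear
   extrapolation beyond the outer landmarks (`learnLandmarks()`,
   `standardizeIntensities()`). The mapping is strictly order-preserving.
   A passthrough mode (`standardize = FALSE`) skips the step.
2. **Mask conditioning.** Fractional lesion masks are trilinearly
   resampled and binarized at 0.5 (values exactly 0.5 are kept), so
   interpolation cannot enlarge a mask
   (`resampleAndBinarizeMask()`). Connected components (26-neighbourhood)
   strictly larger than 100 voxels survive the size filter
   (`labelAndFilterLesions()`); the filter runs in the mask's native grid,
   before any resampling-dependent count could change.
3. **Reference tissues.** A voxel belongs to a tissue when its partial
   volume exceeds 0.5; WM membership excludes every lesion voxel, even
   those below the size filter (`tissueMedians()`). Medians of even-sized
   sets are the mean of the two middle values throughout.
4. **Features.** Per lesion: voxel count, volume (count x voxel volume,
   mm^3), median intensity per sequence, and the standardized intensity
   (lesion median / tissue median) against WM, GM and CSF. A ratio of 1
   means the lesion does not stand out from that tissue.
5. **Typing.** K-means with K = 2 on the raw, unscaled (FSPGR, SE, FLAIR)
   medians pooled across subjects, Lloyd iterations capped at 10, then a
   final classify pass. Cluster 1 is canonically the one with the lower
   FSPGR center. Per-feature influence is the one-way ANOVA F of the
   feature across the final labels, df (1, n - 2).
6. **Standardized lesion distance.** Per subject and sequence, 5000
   reference voxels are drawn with replacement from the WM intensity pool;
   each yields a mean distance d(r) = mean(I_wm)/r. A lesion's d(median)
   is standardized against the moments of that empirical null,
   z = (d - mean)/sd (n-1 denominator). Exceedance is one-sided at
   z > 2.3, reported per cluster and sequence.
7. **Clinical association.** Spearman rank correlations (average-rank
   ties, two-sided t-approximation p) between per-subject cluster burden
   (counts, volumes, totals) and clinical covariates, Bonferroni-adjusted
   over all cells of the reported grid: p_adj = min(1, m p). Constant
   variables are flagged and excluded from the family size m. One-sample
   Wilcoxon signed-rank tests compare WM-relative ratios against unity
   (tie-corrected normal approximation with continuity correction; ratios
   below 1 give negative Z), and a Mann-Whitney U (tie-corrected, with
   continuity correction; U counts pairs with group A larger, ties as one
   half) contrasts the SE and FSPGR ratio distributions.

## Design choices where the design was open

Several operational details are not fixed by the procedure itself; the
package resolves them as follows and exposes each as a parameter where it
matters.

* **Standardization method.** Decile-landmark piecewise-linear
  standardization, the canonical histogram-landmark approach for MR
  intensity normalization. Degenerate (constant) volumes are rejected
  rather than silently mapped.
* **"Larger than 100 voxels"** is read strictly (> 100): a 100-voxel
  component is dropped, a 101-voxel one kept.
* **Threshold "at 0.5"** keeps values exactly at 0.5, matching the usual
  semantics of mask thresholding tools.
* **Ratio direction.** "Average ratio of WM voxel intensities and the
  reference" is implemented as mean(wm)/reference by default, so darker
  (hypointense) references yield larger distances and positive z — the
  direction in which an exceedance threshold for black holes makes sense.
  The reciprocal direction is available (`direction = "ref_over_wm"`).
* **Z conversion.** Moment standardization against the empirical null
  (not an empirical-quantile transform): "converted to Z-scores" is taken
  at face value. The looped mean-of-ratios equals mean(wm)/r
  algebraically; the closed form is used for the 5000-fold null and is
  tested against the literal loop at 1e-9 relative tolerance.
* **Bootstrap with replacement**, because subject WM pools may hold fewer
  than 5000 voxels on small grids.
* **K-means initialization.** The fit must be deterministic and should
  reliably reach the global 2-partition optimum. A single deterministic
  start (e.g. the farthest pair) demonstrably gets trapped in local optima
  on small inputs, so `fitKMeans2()` uses a deterministic multi-start:
  sweep the n - 1 ordered splits along a fixed set of data-derived
  directions (principal components, their pairwise sums and differences,
  the coordinate axes, the farthest-pair direction), refine each start
  with Lloyd (<= 10 iterations) and keep the lowest within-cluster sum of
  squares. On inputs larger than 100 lesions only the 12 most promising
  splits per direction (by a prefix-sum WCSS sweep) are refined.
  Convergence: no label change, or total center shift below 1e-9.
* **Features are not rescaled before clustering**; the raw intensity units
  drive the distances, which is what makes FSPGR (largest between-class
  gap in absolute units) dominate the cluster formation.
* **Bonferroni** is used for multiplicity: the reported grids show
  adjusted p values capped at exactly 1, which is Bonferroni's signature.
  The family is every cell computed in one run.

## The phantom generator

No images are distributed with the cohort this analysis targets, so the
package generates synthetic subjects with the statistical structure the
analysis assumes (`cohortSpec()`, `generateSubject()`,
`generateCohort()`; `simulateCohortTruth()` replays the per-lesion truth
without rendering voxels).

**Geometry.** A miniature head: three concentric ellipsoidal compartments
(WM core, GM shell, CSF shell) with smooth partial-volume transitions
(transition width 0.05 in normalized radius), on a 96 x 96 x 64 grid of
1 mm isotropic voxels by default. One millimetre voxels make voxel counts
and mm^3 volumes coincide, so the 100-voxel filter is a 100 mm^3 filter.
Lesions are axis-aligned ellipsoids with log-uniform voxel counts on
[60, 2000] (mean ~550; the range deliberately straddles the filter) and
mild random anisotropy, placed fully inside WM-dominant voxels without
overlap — large lesions first, random centres with a bounded retry, then
an exhaustive scan of WM centres; an impossible packing errors out.

**Intensities.** Tissue locations were chosen once to satisfy the required
orderings — on FSPGR (WM 4800, GM 3000, CSF 800) and SE (WM 2000, GM 1400,
CSF 600) every lesion lies strictly between GM and WM; on FLAIR (WM 2200,
GM 2400, CSF 300) lesions are hyperintense — and to place class-2 SE
medians near the WM median, so class-2 lesions "disappear" on SE. The two
lesion classes sample their per-sequence medians from truncated normals
centred on the reported final cluster centers (class 1: FSPGR 3525.20, SE
1701.23, FLAIR 2575.23; class 2: 4280.42, 1887.77, 2555.67), truncated to
the (GM, WM) band on FSPGR/SE and to (WM, Inf) on FLAIR. Spreads (150/110
FSPGR, 150/65 SE, 220/240 FLAIR) were set so the classes are disjoint on
FSPGR, adjacent on SE, and indistinguishable on FLAIR, mirroring the
reported per-cluster ranges qualitatively. Voxel noise is Gaussian with sd
equal to 3% of the local noise-free intensity — small enough to preserve
all orderings. Cohort scale: 79 subjects, Poisson(694/79) lesions each,
class-2 probability 470/694.

**Clinical coupling.** Covariates attach to the *analyzable* class-2
burden (lesions above the filter) through a Gaussian copula: the burden is
rank-transformed to normal scores, a latent Gaussian with Pearson
correlation r = 2 sin(pi rho / 6) is drawn — the value that yields
population Spearman rho under a Gaussian copula — and mapped through each
covariate's marginal quantile function. Default targets: rho = +0.30
(class-2 count with EDSS), +0.33 (class-2 count with disease duration),
-0.51 (class-2 volume with normalized brain volume). Marginals: disease
duration truncated-normal (mean 12.34, sd 7.44 years, >= 0); EDSS a
truncated-normal latent mapped to the 0-10 scale in 0.5 steps (median
~2); NBV Gaussian around 1.5e6 (sd 8e4) in SIENAX-like arbitrary units;
relapse counts independent Poisson. Class-1 burden receives no injected
effect — and because lesion counts are thinned Poisson draws, class-1 and
class-2 counts are independent, so the class-1 correlations form a true
null grid.

**Reproducibility.** One master seed; per-subject seeds derive from it by
a fixed counter scheme (seed_i = master + 99991 i mod 2^31 - 19), and the
clinical table uses counter 0. Identical specs reproduce bit-identical
volumes, tables and (gzip being deterministic here) fixture files.

**What the phantom does not emulate.** MR physics (TE/TR, flip angles),
bias fields, registration misalignment, anatomical lesion priors
(placement is uniform in WM), contrast-enhancing acute lesions,
non-ellipsoidal lesion shapes, and realistic brain surface-to-volume
ratio. The last point has a visible consequence: WM-dominant voxels
include partial-volume boundary voxels whose mixed intensities form a
dark tail, and on a miniature brain that tail is proportionally larger
than in vivo. The null calibration of the Z = 2.3 cutoff (pseudo-lesions
drawn from WM itself) therefore sits near 4-5% exceedance rather than the
Gaussian 1.1% — still within the cutoff's nominal 5% — and passing tests
on phantoms certify the machinery and its calibration, not performance on
real scanner data.

## Problem sizes and budgets

The test suite exercises the full 79-subject default cohort once for the
cluster-recovery check, 20 replicate cohorts at truth level (no voxel
rendering) for the correlation-recovery check, and 48 mm-scale grids with
3-5 subjects elsewhere; these sizes keep the complete suite around two
minutes while leaving every cohort-level property measurable. The
acceptance script regenerates the full default cohort and the
null-calibration simulation (10 subjects x 2000 pseudo-lesions) in under
two minutes.

## Known limitations

* The per-lesion feature set is intensity-only (medians and ratios); no
  texture, shape or location features.
* The Mann-Whitney U of the real study (U = 76491.5) and the absolute
  exceedance percentages depend on the real images' intensity
  distributions and are not reproducible from synthetic data; the package
  reports its own computed values.
* `generateCohort()` keeps all subjects in memory; use the streaming
  `analyzeCohort()` for full-size cohorts.
* The staged `runPipeline()` holds the simulated cohort in memory across
  stages; its file contracts are designed for modest test cohorts.
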