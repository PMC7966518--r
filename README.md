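# bhtyper

Intensity-based typing of T1-hypointense lesions ("black holes") in
multiple sclerosis, from co-registered FSPGR, SE and FLAIR MRI.

## The problem

Black holes — white-matter lesions that appear hypointense on T1-weighted
images — mark axonal loss and carry clinical weight in MS. They are
traditionally read on spin-echo (SE) T1 images, but fast spoiled
gradient-echo (FSPGR) sequences show them with better contrast. Not all
black holes behave alike: lesions that stand out sharply on FSPGR may be
nearly invisible on SE, and the two kinds relate differently to disability
and atrophy. `bhtyper` is aimed at neuroimaging researchers who want to

1. separate lesions into two intensity-defined classes by K-means
   clustering of per-lesion median intensities on (FSPGR, SE, FLAIR),
2. quantify each lesion's separability from the subject's own
   normal-appearing white matter with a bootstrap **standardized lesion
   distance** Z statistic, and
3. relate class-wise lesion burden (count, volume) to clinical covariates
   (EDSS, disease duration, relapses, normalized brain volume) with
   rank correlations under multiple-comparison control.

Because the cohort this analysis is calibrated against deposits no images,
the package ships a synthetic multi-contrast phantom generator
(`cohortSpec()`, `generateCohort()`) that emulates the study conditions —
79 subjects, ~694 lesions in two intensity classes, injected clinical
effects — and is itself first-class, tested code.

## The statistic

For a subject with white-matter voxel intensities \(I_1,\dots,I_n\) (lesion
voxels excluded) and a reference intensity \(r\), the **mean distance** is

    d(r) = (1/n) * sum_i ( I_i / r )  =  mean(I) / r ,

so dark references score high. A per-subject null distribution is built by
drawing B = 5000 reference voxels with replacement from the WM pool and
computing d for each; a lesion with median intensity m is then standardized
against that null:

    z = ( d(m) - mean(d_null) ) / sd(d_null) .

Lesions with z > 2.3 are counted as clearly separable from white matter.
Upstream, volumes are standardized by decile-landmark piecewise-linear
mapping, lesion masks are thresholded at 0.5 after trilinear resampling,
and only lesions larger than 100 voxels enter the analysis. Clustering is
Lloyd K-means (K = 2, at most 10 iterations, deterministic multi-start
initialization, final classify pass) on the raw medians; per-feature
influence is the one-way ANOVA F across the final labels. Burden-clinical
association uses Spearman rank correlation with Bonferroni correction over
the whole reported grid.

## Worked example

```r
library(bhtyper)
spec <- cohortSpec(nSubjects = 5, gridShape = c(64, 64, 48),
                   meanLesionsPerSubject = 8, lesionSizeRange = c(60, 400),
                   masterSeed = 42)
res <- analyzeCohort(spec, nullSamples = 1000)
res$model
```

```
ClusterModel2: 32 lesions -> 13 / 19 (converged: TRUE, iterations: 1)
  centers:
         median_fspgr median_se median_flair
cluster1      3566.63   1711.88      2557.94
cluster2      4329.32   1865.44      2591.60
  feature F: median_fspgr=245.85, median_se=26.91, median_flair=0.21
```

Five phantom subjects yielded 32 lesions above the size filter. The two
clusters sit at the calibrated class locations: cluster 1 (the darker,
classic black holes) near FSPGR 3567, cluster 2 near 4329. FSPGR dominates
cluster formation (F = 245.9) while FLAIR is negligible (F = 0.21) — the
FLAIR medians of the two classes nearly coincide by design.

```r
res$exceedance
```

```
  cluster sequence  n n_exceeding percentage
1       1    fspgr 13          13  100.00000
2       1       se 13          10   76.92308
3       1    flair 13           0    0.00000
4       2    fspgr 19           3   15.78947
5       2       se 19           2   10.52632
6       2    flair 19           0    0.00000
```

Every cluster-1 lesion exceeds the standardized lesion distance Z = 2.3 on
FSPGR and ~77% do on SE; cluster-2 lesions rarely clear the cutoff, i.e.
they blend into the white matter, especially on SE.

```r
res$tests$wilcoxon_wm_fspgr
#> wilcoxon_signed_rank_vs_1: statistic Z = -4.9272, p = 8.343e-07 (n = 32)
subset(res$correlations, burden == "cl2_count" & clinical == "edss")
#>       burden clinical       rho     p_raw n p_adjusted
#> 11 cl2_count     edss 0.2236068 0.7176856 5          1
```

The WM-relative ratios sit significantly below unity (negative Z: lesions
darker than WM), and at n = 5 subjects the injected burden-EDSS
association is visible in rho but, correctly, nowhere near significant
after Bonferroni correction — recovering it takes the full 79-subject
design (see below).

The staged, file-based equivalent (NIfTI/CSV/JSON artifacts plus a
checksummed run manifest) is `runPipeline(config, outDir)`; fixtures for
external tools can be written with `writeFixtures()`.

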