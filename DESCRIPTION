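Package: bhtyper
Title: Intensity-Based Typing of T1-Hypointense Lesions in Multiple Sclerosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for separating T1-hypointense multiple sclerosis lesions
    (black holes) into intensity-defined classes from co-registered FSPGR, SE
    and FLAIR volumes. Implements landmark-based intensity standardization,
    lesion-mask conditioning (trilinear resampling with threshold/binarize and
    a minimum-size filter), per-lesion median intensity features, two-cluster
    K-means typing with per-feature influence statistics, a bootstrap
    standardized-lesion-distance Z statistic built from subject-wise white
    matter voxels, and rank-based association of class-wise lesion burden with
    clinical covariates. Includes a synthetic multi-contrast phantom generator
    that emulates a cohort with two lesion intensity classes and injected
    clinical effects, used for calibration and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'clinical.R'
    'clinstats.R'
    'cluster.R'
    'preprocess.R'
    'features.R'
    'phantom.R'
    'slz.R'
    'pipeline.R'
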