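#' @import methods
NULL

.SEQUENCES <- c("fspgr", "se", "flair")
.TISSUES <- c("wm", "gm", "csf")

#' CohortSpec: parameters of the synthetic multi-contrast cohort
#'
#' Describes the statistical structure of a simulated relapsing-remitting MS
#' cohort: grid geometry, per-tissue voxel intensities on the three sequences
#' (FSPGR, SE, FLAIR), the two lesion intensity classes, the lesion size
#' distribution, and the rank-correlation effect sizes linking class-2 lesion
#' burden to clinical covariates.
#'
#' @slot nSubjects number of subjects in the cohort.
#' @slot gridShape integer vector of length 3, voxels per axis.
#' @slot voxelSize numeric vector of length 3, mm per axis.
#' @slot tissueIntensities 3 x 3 numeric matrix (rows = sequences fspgr/se/
#'   flair, columns = tissues wm/gm/csf) of tissue intensity locations.
#' @slot lesionClassLocation 2 x 3 numeric matrix (rows = classes, columns =
#'   sequences) of lesion median-intensity locations.
#' @slot lesionClassSpread 2 x 3 numeric matrix of lesion median-intensity
#'   spreads (standard deviations before truncation).
#' @slot meanLesionsPerSubject Poisson rate of lesions per subject.
#' @slot lesionSizeRange numeric(2); lesion voxel counts are log-uniform on
#'   this interval, which must straddle the analysis size filter.
#' @slot class2Fraction probability that a lesion belongs to class 2.
#' @slot effectSizes named numeric vector with elements \code{edss} (target
#'   Spearman rho of class-2 lesion count with EDSS), \code{duration} (class-2
#'   count with disease duration) and \code{nbv} (class-2 lesion volume with
#'   normalized brain volume).
#' @slot noiseFraction per-voxel Gaussian noise standard deviation as a
#'   fraction of the local noise-free intensity.
#' @slot masterSeed integer master seed; all per-subject seeds derive from it.
#' @seealso [cohortSpec()] for the user-facing constructor with defaults
#'   calibrated to the study conditions.
#' @export
setClass("CohortSpec",
  representation(
    nSubjects = "integer",
    gridShape = "integer",
    voxelSize = "numeric",
    tissueIntensities = "matrix",
    lesionClassLocation = "matrix",
    lesionClassSpread = "matrix",
    meanLesionsPerSubject = "numeric",
    lesionSizeRange = "numeric",
    class2Fraction = "numeric",
    effectSizes = "numeric",
    noiseFraction = "numeric",
    masterSeed = "integer"
  )
)

setValidity("CohortSpec", function(object) {
  msg <- character(0)
  if (length(object@nSubjects) != 1L || is.na(object@nSubjects) ||
      object@nSubjects < 1L)
    msg <- c(msg, "nSubjects: must be a single integer >= 1")
  if (length(object@gridShape) != 3L || any(object@gridShape < 8L))
    msg <- c(msg, "gridShape: must be three axis lengths, each >= 8")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize: must be three positive extents (mm)")
  ti <- object@tissueIntensities
  if (!identical(dim(ti), c(3L, 3L)) ||
      !identical(rownames(ti), .SEQUENCES) ||
      !identical(colnames(ti), .TISSUES))
    msg <- c(msg, "tissueIntensities: must be a 3x3 matrix with rows fspgr/se/flair and columns wm/gm/csf")
  loc <- object@lesionClassLocation
  spr <- object@lesionClassSpread
  if (!identical(dim(loc), c(2L, 3L)) || !identical(colnames(loc), .SEQUENCES))
    msg <- c(msg, "lesionClassLocation: must be a 2x3 matrix with columns fspgr/se/flair")
  if (!identical(dim(spr), c(2L, 3L)) || !identical(colnames(spr), .SEQUENCES))
    msg <- c(msg, "lesionClassSpread: must be a 2x3 matrix with columns fspgr/se/flair")
  if (length(msg) == 0L) {
    if (any(spr <= 0))
      msg <- c(msg, "lesionClassSpread: all spreads must be > 0")
    # T1-weighted contrast: lesions darker than WM, brighter than GM
    for (s in c("fspgr", "se")) {
      if (!all(loc[, s] > ti[s, "gm"] & loc[, s] < ti[s, "wm"]))
        msg <- c(msg, sprintf(
          "lesionClassLocation: on %s, class locations must lie strictly between the GM and WM locations", s))
    }
    if (!all(loc[, "flair"] > ti["flair", "wm"]))
      msg <- c(msg, "lesionClassLocation: on flair, class locations must lie above the WM location")
  }
  if (length(object@meanLesionsPerSubject) != 1L ||
      object@meanLesionsPerSubject < 0)
    msg <- c(msg, "meanLesionsPerSubject: must be a single rate >= 0")
  if (length(object@lesionSizeRange) != 2L ||
      any(object@lesionSizeRange < 1) || diff(object@lesionSizeRange) < 0)
    msg <- c(msg, "lesionSizeRange: must be an increasing pair of voxel counts >= 1")
  if (length(object@class2Fraction) != 1L || is.na(object@class2Fraction) ||
      object@class2Fraction < 0 || object@class2Fraction > 1)
    msg <- c(msg, "class2Fraction: must lie in [0, 1]")
  es <- object@effectSizes
  if (!all(c("edss", "duration", "nbv") %in% names(es)) ||
      any(abs(es) > 1))
    msg <- c(msg, "effectSizes: must name edss, duration and nbv, each in [-1, 1]")
  if (length(object@noiseFraction) != 1L || object@noiseFraction < 0)
    msg <- c(msg, "noiseFraction: must be a single value >= 0")
  if (length(object@masterSeed) != 1L || is.na(object@masterSeed))
    msg <- c(msg, "masterSeed: must be a single integer")
  if (length(msg)) msg else TRUE
})

#' SubjectPhantom: one simulated subject
#'
#' Holds the three co-registered intensity volumes, the lesion label grid,
#' the WM/GM/CSF partial-volume maps, and the generating truth (per-lesion
#' class and sampled medians) for a single synthetic subject.
#'
#' @slot subjectId character identifier.
#' @slot volumes named list of three 3D numeric arrays (fspgr, se, flair).
#' @slot lesionLabels 3D integer array; 0 = background, k = lesion k.
#' @slot tissueMaps named list of three 3D partial-volume arrays (wm, gm,
#'   csf), values in [0, 1], summing to at most 1 per voxel.
#' @slot voxelSize numeric(3), mm per axis.
#' @slot truth data.frame with one row per generated lesion: lesion_id,
#'   class, voxel_count, and the sampled median intensity per sequence.
#' @export
setClass("SubjectPhantom",
  representation(
    subjectId = "character",
    volumes = "list",
    lesionLabels = "array",
    tissueMaps = "list",
    voxelSize = "numeric",
    truth = "data.frame"
  )
)

setValidity("SubjectPhantom", function(object) {
  msg <- character(0)
  if (!identical(names(object@volumes), .SEQUENCES))
    msg <- c(msg, "volumes must be a named list fspgr/se/flair")
  if (!identical(names(object@tissueMaps), .TISSUES))
    msg <- c(msg, "tissueMaps must be a named list wm/gm/csf")
  dims <- lapply(c(object@volumes, object@tissueMaps), dim)
  dims <- c(dims, list(dim(object@lesionLabels)))
  if (length(msg) == 0L &&
      !all(vapply(dims, identical, logical(1), y = dims[[1]])))
    msg <- c(msg, "all grids must share the same shape")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be three positive extents")
  if (length(msg) == 0L) {
    pv <- object@tissueMaps
    rng <- range(vapply(pv, function(m) range(m), numeric(2)))
    if (rng[1] < 0 || rng[2] > 1 + 1e-8)
      msg <- c(msg, "partial volumes must lie in [0, 1]")
    if (max(pv$wm + pv$gm + pv$csf) > 1 + 1e-8)
      msg <- c(msg, "partial volumes must sum to <= 1 per voxel")
    lab <- object@lesionLabels
    k <- max(lab)
    if (min(lab) < 0)
      msg <- c(msg, "lesion labels must be non-negative")
    if (k > 0 && !all(seq_len(k) %in% unique(as.vector(lab))))
      msg <- c(msg, "lesion labels must be contiguous positive integers")
    if (k != nrow(object@truth))
      msg <- c(msg, "truth must have one row per labelled lesion")
  }
  if (length(msg)) msg else TRUE
})

#' TissueMedians: per-sequence reference-tissue summary for one subject
#'
#' @slot subjectId character identifier.
#' @slot medians 3 x 3 numeric matrix (rows = sequences, columns = tissues)
#'   of median tissue intensities; lesion voxels are excluded from WM.
#' @slot wmIntensities named list (per sequence) of the retained white-matter
#'   voxel intensities, used to build the bootstrap null distribution.
#' @export
setClass("TissueMedians",
  representation(
    subjectId = "character",
    medians = "matrix",
    wmIntensities = "list"
  )
)

setValidity("TissueMedians", function(object) {
  msg <- character(0)
  if (!identical(rownames(object@medians), .SEQUENCES) ||
      !identical(colnames(object@medians), .TISSUES))
    msg <- c(msg, "medians must be a 3x3 matrix with rows fspgr/se/flair and columns wm/gm/csf")
  else if (any(object@medians <= 0))
    msg <- c(msg, "all tissue medians must be > 0")
  if (!identical(names(object@wmIntensities), .SEQUENCES) ||
      any(vapply(object@wmIntensities, length, integer(1)) == 0L))
    msg <- c(msg, "wmIntensities must hold a non-empty vector per sequence")
  if (length(msg)) msg else TRUE
})

#' ClusterModel2: fitted two-cluster K-means model on lesion medians
#'
#' @slot centers 2 x 3 numeric matrix of final cluster centers (rows =
#'   clusters, columns = sequences); cluster 1 is canonically the cluster
#'   with the lower FSPGR center.
#' @slot labels integer vector in {1, 2}, one per lesion row.
#' @slot sizes integer(2), lesions per cluster.
#' @slot featureF named numeric(3), one-way ANOVA F of each feature across
#'   the final labels (df 1, n - 2).
#' @slot iterations Lloyd iterations used by the selected start.
#' @slot converged logical; TRUE if the selected start converged before the
#'   iteration cap.
#' @export
setClass("ClusterModel2",
  representation(
    centers = "matrix",
    labels = "integer",
    sizes = "integer",
    featureF = "numeric",
    iterations = "integer",
    converged = "logical"
  )
)

setValidity("ClusterModel2", function(object) {
  msg <- character(0)
  if (!identical(dim(object@centers), c(2L, 3L)))
    msg <- c(msg, "centers must be 2 x 3")
  if (!all(object@labels %in% c(1L, 2L)))
    msg <- c(msg, "labels must be in {1, 2}")
  if (sum(object@sizes) != length(object@labels))
    msg <- c(msg, "sizes must sum to the number of lesions")
  if (object@iterations > 10L)
    msg <- c(msg, "iterations must be <= 10")
  if (length(msg)) msg else TRUE
})

#' NullDistribution: bootstrap white-matter null for one subject x sequence
#'
#' The empirical distribution of mean-ratio distances obtained by repeatedly
#' sampling a reference voxel from the subject's white-matter intensities.
#'
#' @slot subjectId character identifier.
#' @slot sequence sequence tag ("fspgr", "se" or "flair").
#' @slot distances numeric vector of bootstrap mean-distance values.
#' @slot nullMean mean of \code{distances}.
#' @slot nullSd standard deviation of \code{distances} (n - 1 denominator).
#' @export
setClass("NullDistribution",
  representation(
    subjectId = "character",
    sequence = "character",
    distances = "numeric",
    nullMean = "numeric",
    nullSd = "numeric"
  )
)

setValidity("NullDistribution", function(object) {
  msg <- character(0)
  if (length(object@distances) < 2L)
    msg <- c(msg, "a null distribution needs at least 2 distances")
  if (any(object@distances <= 0))
    msg <- c(msg, "all distances must be > 0")
  if (!is.na(object@nullSd) && object@nullSd <= 0)
    msg <- c(msg, "degenerate null: sd of distances must be > 0")
  if (!object@sequence %in% .SEQUENCES)
    msg <- c(msg, "sequence must be one of fspgr/se/flair")
  if (length(msg)) msg else TRUE
})
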