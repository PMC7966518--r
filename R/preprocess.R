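#' @include AllClasses.R utils.R
NULL

#' Learn cohort landmark intensities for one sequence
#'
#' Computes, for each requested percentile, the mean of that percentile
#' across all supplied volumes. The resulting landmark map defines the
#' standard intensity scale onto which individual volumes are mapped by
#' [standardizeIntensities()] (decile-landmark piecewise-linear
#' standardization).
#'
#' @param volumeList list of 3D numeric arrays (one per subject) from the
#'   same sequence.
#' @param percentiles strictly increasing percentiles in (0, 100); default
#'   the deciles 10, 20, ..., 90.
#' @return A list with elements \code{percentiles} and \code{landmarks}
#'   (mean landmark intensity per percentile).
#' @export
learnLandmarks <- function(volumeList, percentiles = seq(10, 90, by = 10)) {
  if (!length(volumeList)) stop("need at least one volume")
  if (any(percentiles <= 0) || any(percentiles >= 100) ||
      any(diff(percentiles) <= 0))
    stop("percentiles must be strictly increasing and in (0, 100)")
  lm <- vapply(volumeList, function(v) {
    q <- stats::quantile(as.vector(v), percentiles / 100, names = FALSE)
    if (any(diff(q) <= 0))
      stop("degenerate landmarks: volume percentiles are not strictly increasing (constant or near-constant volume)")
    q
  }, numeric(length(percentiles)))
  lm <- if (is.matrix(lm)) rowMeans(lm) else lm
  list(percentiles = percentiles, landmarks = as.numeric(lm))
}

#' Map a volume onto a standard landmark scale
#'
#' Piecewise-linear mapping of the volume's own percentile landmarks onto
#' the standard landmarks, with linear extrapolation beyond the outermost
#' landmarks using the adjacent segment slopes. The mapping is strictly
#' order-preserving.
#'
#' @param volume 3D numeric array.
#' @param landmarkMap landmark map from [learnLandmarks()] for the same
#'   sequence.
#' @return The standardized volume (same shape).
#' @export
standardizeIntensities <- function(volume, landmarkMap) {
  std <- landmarkMap$landmarks
  pct <- landmarkMap$percentiles
  if (any(diff(std) <= 0))
    stop("landmark map is not strictly increasing")
  own <- stats::quantile(as.vector(volume), pct / 100, names = FALSE)
  if (any(diff(own) <= 0))
    stop("degenerate landmarks: volume percentiles are not strictly increasing")
  v <- as.vector(volume)
  y <- stats::approx(own, std, xout = v, rule = 2)$y
  m <- length(own)
  sl1 <- (std[2] - std[1]) / (own[2] - own[1])
  slm <- (std[m] - std[m - 1]) / (own[m] - own[m - 1])
  lo <- v < own[1]
  hi <- v > own[m]
  y[lo] <- std[1] + (v[lo] - own[1]) * sl1
  y[hi] <- std[m] + (v[hi] - own[m]) * slm
  array(y, dim(volume))
}

#' Resample a fractional mask and binarize at a threshold
#'
#' Trilinearly resamples a fractional (partial-volume) mask onto a target
#' grid, then binarizes: voxels with interpolated value greater than or
#' equal to the threshold are set to 1, all others to 0. Thresholding after
#' interpolation avoids the mask enlargement that interpolation alone would
#' introduce.
#'
#' Source and target grids are aligned in physical space at the corner of
#' the field of view; the voxel centre of target voxel i sits at physical
#' position (i - 0.5) * targetVoxelSize.
#'
#' @param mask 3D numeric array with values in [0, 1].
#' @param targetDim integer(3), target grid shape.
#' @param sourceVoxelSize,targetVoxelSize numeric(3) voxel extents (mm).
#' @param threshold binarization threshold (default 0.5; values exactly at
#'   the threshold are kept).
#' @return 3D integer array of 0/1 values with shape \code{targetDim}.
#' @export
resampleAndBinarizeMask <- function(mask, targetDim,
                                    sourceVoxelSize = c(1, 1, 1),
                                    targetVoxelSize = sourceVoxelSize,
                                    threshold = 0.5) {
  if (min(mask) < 0 || max(mask) > 1)
    stop("mask values must lie in [0, 1]")
  if (length(targetDim) != 3L || any(targetDim < 1L))
    stop("targetDim must be three positive axis lengths")
  if (any(sourceVoxelSize <= 0) || any(targetVoxelSize <= 0))
    stop("incompatible grids: voxel sizes must be positive")
  srcExtent <- dim(mask) * sourceVoxelSize
  tgtExtent <- targetDim * targetVoxelSize
  if (any(abs(srcExtent - tgtExtent) > pmax(sourceVoxelSize, targetVoxelSize)))
    stop("incompatible grids: source and target fields of view do not match")
  tg <- expand.grid(i = seq_len(targetDim[1]), j = seq_len(targetDim[2]),
                    k = seq_len(targetDim[3]))
  # physical position of target voxel centres, mapped to source index space
  coords <- cbind(((tg$i - 0.5) * targetVoxelSize[1]) / sourceVoxelSize[1] + 0.5,
                  ((tg$j - 0.5) * targetVoxelSize[2]) / sourceVoxelSize[2] + 0.5,
                  ((tg$k - 0.5) * targetVoxelSize[3]) / sourceVoxelSize[3] + 0.5)
  vals <- trilinearSample(mask, coords)
  out <- array(0L, targetDim)
  out[vals >= threshold] <- 1L
  out
}

#' Label lesions and apply the minimum-size filter
#'
#' If the input is a binary mask, its 26-connected components are labelled
#' first; a grid of positive integer labels is taken as a pre-existing
#' labelling. Components with strictly more than \code{minLesionVoxels}
#' voxels are retained and relabelled compactly (1..K), preserving the
#' original label order; all other voxels become 0.
#'
#' @param labels 3D non-negative integer (or binary) array.
#' @param minLesionVoxels retention threshold; a component survives only if
#'   its voxel count exceeds this value (default 100).
#' @return 3D integer array of filtered, compact labels. The attribute
#'   \code{keptLabels} maps each new label to the original component label.
#' @export
labelAndFilterLesions <- function(labels, minLesionVoxels = 100L) {
  if (min(labels) < 0 || any(labels != round(labels)))
    stop("labels must be a non-negative integer grid")
  vals <- unique(as.vector(labels))
  if (all(vals %in% c(0, 1))) labels <- labelComponents3D(labels)
  storage.mode(labels) <- "integer"
  if (max(labels) == 0L) {
    out <- array(0L, dim(labels))
    attr(out, "keptLabels") <- integer(0)
    return(out)
  }
  counts <- tabulate(labels[labels > 0L], nbins = max(labels))
  kept <- which(counts > minLesionVoxels)
  map <- integer(max(labels) + 1L)  # old label + 1 -> new label
  map[kept + 1L] <- seq_along(kept)
  out <- array(map[labels + 1L], dim(labels))
  attr(out, "keptLabels") <- kept
  out
}

#' Reference-tissue medians and white-matter voxel intensities
#'
#' A voxel belongs to a tissue when that tissue's partial volume exceeds
#' 0.5; white-matter membership additionally excludes every lesion voxel, so
#' lesions cannot contaminate the normal-appearing WM summary. Returns the
#' per-sequence median intensity of each tissue and the retained multiset of
#' WM voxel intensities used to build bootstrap null distributions.
#'
#' @param volumeBySequence named list of the three intensity volumes
#'   (fspgr, se, flair).
#' @param tissueMaps named list of WM/GM/CSF partial-volume arrays.
#' @param lesionMask logical or 0/1 array marking all lesion voxels
#'   (unfiltered; even sub-threshold lesions are excluded from WM).
#' @param subjectId identifier carried through to the result.
#' @return A [TissueMedians-class] object.
#' @export
tissueMedians <- function(volumeBySequence, tissueMaps, lesionMask,
                          subjectId = "subject") {
  stopifnot(identical(names(volumeBySequence), .SEQUENCES))
  member <- list(
    wm = tissueMaps$wm > 0.5 & !(lesionMask != 0),
    gm = tissueMaps$gm > 0.5,
    csf = tissueMaps$csf > 0.5)
  for (t in .TISSUES) {
    if (!any(member[[t]]))
      stop("empty tissue class: no voxels with ", t, " partial volume > 0.5")
  }
  med <- matrix(NA_real_, 3, 3, dimnames = list(.SEQUENCES, .TISSUES))
  wmInt <- list()
  for (s in .SEQUENCES) {
    v <- volumeBySequence[[s]]
    for (t in .TISSUES) med[s, t] <- stats::median(v[member[[t]]])
    wmInt[[s]] <- as.numeric(v[member$wm])
  }
  new("TissueMedians", subjectId = subjectId, medians = med,
      wmIntensities = wmInt)
}
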