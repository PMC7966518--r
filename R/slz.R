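#' @include AllClasses.R
NULL

#' Mean-ratio distance between a reference intensity and the WM voxels
#'
#' The average, over all white-matter voxels, of the ratio of the WM voxel
#' intensity to the reference intensity (default direction), i.e.
#' mean(wm / reference), which equals mean(wm) / reference. With
#' \code{direction = "ref_over_wm"} the reciprocal ratio is averaged
#' instead. Darker references therefore give larger distances under the
#' default direction, so hypointense lesions score high.
#'
#' @param reference a positive reference intensity (a sampled WM voxel or a
#'   lesion's median intensity).
#' @param wmIntensities non-empty vector of positive WM voxel intensities.
#' @param direction "wm_over_ref" (default) or "ref_over_wm".
#' @return The mean-ratio distance (dimensionless, > 0).
#' @examples
#' meanDistance(2, c(2, 4, 6))  # (1 + 2 + 3) / 3 = 2
#' @export
meanDistance <- function(reference, wmIntensities,
                         direction = c("wm_over_ref", "ref_over_wm")) {
  direction <- match.arg(direction)
  if (length(reference) != 1L || !is.finite(reference) || reference <= 0)
    stop("reference intensity must be a single positive value")
  if (!length(wmIntensities) || any(wmIntensities <= 0))
    stop("wmIntensities must be non-empty and all positive")
  if (direction == "wm_over_ref") mean(wmIntensities / reference)
  else mean(reference / wmIntensities)
}

#' Bootstrap null distribution of mean distances for one subject
#'
#' Samples \code{nSamples} reference voxels with replacement from the
#' subject's white-matter intensities and computes the mean-ratio distance
#' of each, yielding the subject-specific null distribution against which
#' lesion distances are standardized. Summary moments use the n - 1
#' denominator for the standard deviation.
#'
#' @param wmIntensities non-empty vector of positive WM voxel intensities.
#' @param nSamples number of bootstrap references (default 5000; minimum 2).
#' @param seed integer RNG seed for the resampling.
#' @param direction ratio direction, as in [meanDistance()].
#' @param subjectId,sequence identifiers carried into the result.
#' @return A [NullDistribution-class] object.
#' @export
buildNull <- function(wmIntensities, nSamples = 5000L, seed = 1L,
                      direction = c("wm_over_ref", "ref_over_wm"),
                      subjectId = "subject", sequence = "fspgr") {
  direction <- match.arg(direction)
  if (!length(wmIntensities) || any(wmIntensities <= 0))
    stop("wmIntensities must be non-empty and all positive")
  if (nSamples < 2L) stop("nSamples must be >= 2")
  set.seed(as.integer(seed))
  refs <- wmIntensities[sample.int(length(wmIntensities), nSamples,
                                   replace = TRUE)]
  d <- if (direction == "wm_over_ref") mean(wmIntensities) / refs
       else refs * mean(1 / wmIntensities)
  sdd <- stats::sd(d)
  if (!is.finite(sdd) || sdd == 0)
    stop("degenerate null: all sampled distances identical (constant WM intensities)")
  new("NullDistribution", subjectId = subjectId, sequence = sequence,
      distances = d, nullMean = mean(d), nullSd = sdd)
}

#' Standardized lesion distance (Z) for a set of lesion medians
#'
#' Each lesion's mean-ratio distance to the subject's white matter is
#' converted to a Z score against the subject's bootstrap null:
#' z = (distance - null mean) / null sd. Z therefore measures how far the
#' lesion's intensity sits outside the subject's own WM intensity profile;
#' under the default ratio direction, z increases strictly as the lesion
#' median darkens.
#'
#' @param lesionMedians vector of positive lesion median intensities.
#' @param wmIntensities the subject's WM voxel intensities (same multiset
#'   the null was built from).
#' @param null a [NullDistribution-class] for this subject and sequence.
#' @param direction ratio direction, as in [meanDistance()].
#' @return data.frame with columns lesion_distance and z, one row per
#'   lesion median.
#' @export
lesionZScores <- function(lesionMedians, wmIntensities, null,
                          direction = c("wm_over_ref", "ref_over_wm")) {
  direction <- match.arg(direction)
  stopifnot(is(null, "NullDistribution"))
  if (nullSd(null) <= 0) stop("degenerate null distribution")
  d <- vapply(lesionMedians, meanDistance, numeric(1),
              wmIntensities = wmIntensities, direction = direction)
  data.frame(lesion_distance = d, z = (d - nullMean(null)) / nullSd(null))
}

#' Percentage of lesions exceeding the Z threshold, per cluster x sequence
#'
#' @param zTable data.frame with a \code{cluster_label} column and one
#'   \code{z_<sequence>} column per sequence (e.g. z_fspgr, z_se).
#' @param zThreshold exceedance threshold (default 2.3); the exceedance is
#'   one-sided (z strictly greater than the threshold).
#' @return data.frame with columns cluster, sequence, n, n_exceeding,
#'   percentage.
#' @export
exceedancePercentages <- function(zTable, zThreshold = 2.3) {
  stopifnot("cluster_label" %in% names(zTable))
  zCols <- grep("^z_", names(zTable), value = TRUE)
  if (!length(zCols)) stop("zTable has no z_<sequence> columns")
  rows <- list()
  for (k in sort(unique(zTable$cluster_label))) {
    sub <- zTable[zTable$cluster_label == k, , drop = FALSE]
    if (!nrow(sub)) stop("empty cluster: ", k)
    for (cn in zCols) {
      ne <- sum(sub[[cn]] > zThreshold)
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = k, sequence = sub("^z_", "", cn), n = nrow(sub),
        n_exceeding = ne, percentage = 100 * ne / nrow(sub))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
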