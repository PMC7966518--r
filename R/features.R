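#' @include AllClasses.R preprocess.R
NULL

#' Per-lesion median intensities
#'
#' Computes, for every labelled lesion, the median voxel intensity on each
#' sequence, over that lesion's voxels only.
#'
#' @param volumeBySequence named list of the three intensity volumes.
#' @param filteredLabels 3D integer array of compact lesion labels (1..K).
#' @return data.frame with columns lesion_id, voxel_count and
#'   median_fspgr / median_se / median_flair.
#' @export
lesionMedians <- function(volumeBySequence, filteredLabels) {
  stopifnot(identical(names(volumeBySequence), .SEQUENCES))
  k <- max(filteredLabels)
  if (k < 1L) stop("no lesions in the filtered labelling")
  idx <- which(filteredLabels > 0L)
  lab <- filteredLabels[idx]
  counts <- tabulate(lab, nbins = k)
  if (any(counts == 0L))
    stop("lesion with zero voxels in the labelling: ",
         paste(which(counts == 0L), collapse = ", "))
  out <- data.frame(lesion_id = seq_len(k), voxel_count = counts)
  for (s in .SEQUENCES) {
    v <- volumeBySequence[[s]][idx]
    out[[paste0("median_", s)]] <-
      as.numeric(vapply(split(v, lab), stats::median, numeric(1)))
  }
  out
}

#' Standardized (reference-tissue-relative) lesion intensities
#'
#' Divides each lesion's median intensity by the subject's reference-tissue
#' median on the same sequence. A ratio of 1 means the lesion is
#' indistinguishable from that tissue.
#'
#' @param medians data.frame from [lesionMedians()].
#' @param tm a [TissueMedians-class] object for the same subject.
#' @return The input data.frame with added columns
#'   \code{ratio_<tissue>_<sequence>} for every tissue (wm, gm, csf) and
#'   sequence.
#' @export
standardizedIntensities <- function(medians, tm) {
  stopifnot(is(tm, "TissueMedians"))
  for (t in .TISSUES) {
    for (s in .SEQUENCES) {
      ref <- tm@medians[s, t]
      if (!is.finite(ref) || ref <= 0)
        stop("non-positive ", t, " median on ", s)
      medians[[paste0("ratio_", t, "_", s)]] <-
        medians[[paste0("median_", s)]] / ref
    }
  }
  medians
}

.featureTableColumns <- function() {
  c("subject_id", "lesion_id", "voxel_count", "volume_mm3",
    paste0("median_", .SEQUENCES),
    as.vector(t(outer(.TISSUES, .SEQUENCES,
                      function(t, s) paste0("ratio_", t, "_", s)))))
}

#' Extract the full feature rows for one subject
#'
#' Convenience wrapper combining [lesionMedians()] and
#' [standardizedIntensities()] and adding lesion volumes in mm^3 computed
#' from the native voxel size.
#'
#' @param volumeBySequence named list of the three intensity volumes.
#' @param filteredLabels compact lesion labelling (output of
#'   [labelAndFilterLesions()]).
#' @param tm a [TissueMedians-class] for the subject.
#' @param voxelSize numeric(3), mm per axis.
#' @param subjectId subject identifier.
#' @return data.frame of per-lesion features (one row per surviving lesion),
#'   or an empty, fully-typed data.frame if no lesion survived.
#' @export
extractSubjectFeatures <- function(volumeBySequence, filteredLabels, tm,
                                   voxelSize, subjectId) {
  if (max(filteredLabels) == 0L) {
    out <- stats::setNames(
      as.data.frame(matrix(numeric(0), nrow = 0,
                           ncol = length(.featureTableColumns()))),
      .featureTableColumns())
    out$subject_id <- character(0)
    return(out)
  }
  med <- lesionMedians(volumeBySequence, filteredLabels)
  med <- standardizedIntensities(med, tm)
  med$subject_id <- subjectId
  med$volume_mm3 <- med$voxel_count * prod(voxelSize)
  med[, .featureTableColumns()]
}

#' Assemble the cohort-level lesion feature table
#'
#' Binds per-subject feature rows into a single table with stable ordering
#' (subject id, then lesion id) and a complete header even when empty.
#'
#' @param subjectFeatureList list of data.frames from
#'   [extractSubjectFeatures()].
#' @return data.frame, one row per surviving lesion across the cohort.
#' @export
buildFeatureTable <- function(subjectFeatureList) {
  cols <- .featureTableColumns()
  keep <- Filter(function(df) nrow(df) > 0, subjectFeatureList)
  if (!length(keep)) {
    out <- stats::setNames(
      as.data.frame(matrix(numeric(0), nrow = 0, ncol = length(cols))), cols)
    out$subject_id <- character(0)
    return(out[, cols])
  }
  out <- do.call(rbind, lapply(keep, function(df) df[, cols]))
  key <- paste(out$subject_id, out$lesion_id)
  if (anyDuplicated(key))
    stop("duplicate (subject, lesion) keys: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  out <- out[order(out$subject_id, out$lesion_id), ]
  rownames(out) <- NULL
  out
}
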