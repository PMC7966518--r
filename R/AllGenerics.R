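#' @include AllClasses.R
NULL

#' @rdname accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname accessors
#' @export
setGeneric("volumes", function(x) standardGeneric("volumes"))

#' @rdname accessors
#' @export
setGeneric("lesionLabels", function(x) standardGeneric("lesionLabels"))

#' @rdname accessors
#' @export
setGeneric("tissueMaps", function(x) standardGeneric("tissueMaps"))

#' @rdname accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname accessors
#' @export
setGeneric("lesionTruth", function(x) standardGeneric("lesionTruth"))

#' @rdname accessors
#' @export
setGeneric("tissueMedian", function(x, sequence, tissue)
  standardGeneric("tissueMedian"))

#' @rdname accessors
#' @export
setGeneric("wmIntensities", function(x, sequence)
  standardGeneric("wmIntensities"))

#' @rdname accessors
#' @export
setGeneric("centers", function(x) standardGeneric("centers"))

#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname accessors
#' @export
setGeneric("clusterSizes", function(x) standardGeneric("clusterSizes"))

#' @rdname accessors
#' @export
setGeneric("featureF", function(x) standardGeneric("featureF"))

#' @rdname accessors
#' @export
setGeneric("nullMean", function(x) standardGeneric("nullMean"))

#' @rdname accessors
#' @export
setGeneric("nullSd", function(x) standardGeneric("nullSd"))

#' @rdname accessors
#' @export
setGeneric("nullDistances", function(x) standardGeneric("nullDistances"))

#' Accessors for bhtyper S4 objects
#'
#' Accessor functions for the slots of [SubjectPhantom-class],
#' [TissueMedians-class], [ClusterModel2-class] and
#' [NullDistribution-class] objects.
#'
#' @param x an object of the relevant class.
#' @param sequence sequence tag: "fspgr", "se" or "flair".
#' @param tissue tissue tag: "wm", "gm" or "csf".
#' @return The slot contents: identifiers, arrays, named lists of arrays,
#'   matrices or numeric vectors, depending on the accessor.
#' @name accessors
NULL

#' @rdname accessors
setMethod("subjectId", "SubjectPhantom", function(x) x@subjectId)
#' @rdname accessors
setMethod("subjectId", "TissueMedians", function(x) x@subjectId)
#' @rdname accessors
setMethod("subjectId", "NullDistribution", function(x) x@subjectId)
#' @rdname accessors
setMethod("volumes", "SubjectPhantom", function(x) x@volumes)
#' @rdname accessors
setMethod("lesionLabels", "SubjectPhantom", function(x) x@lesionLabels)
#' @rdname accessors
setMethod("tissueMaps", "SubjectPhantom", function(x) x@tissueMaps)
#' @rdname accessors
setMethod("voxelSize", "SubjectPhantom", function(x) x@voxelSize)
#' @rdname accessors
setMethod("lesionTruth", "SubjectPhantom", function(x) x@truth)
#' @rdname accessors
setMethod("tissueMedian", "TissueMedians", function(x, sequence, tissue) {
  x@medians[match.arg(sequence, .SEQUENCES), match.arg(tissue, .TISSUES)]
})
#' @rdname accessors
setMethod("wmIntensities", "TissueMedians", function(x, sequence) {
  x@wmIntensities[[match.arg(sequence, .SEQUENCES)]]
})
#' @rdname accessors
setMethod("centers", "ClusterModel2", function(x) x@centers)
#' @rdname accessors
setMethod("clusterLabels", "ClusterModel2", function(x) x@labels)
#' @rdname accessors
setMethod("clusterSizes", "ClusterModel2", function(x) x@sizes)
#' @rdname accessors
setMethod("featureF", "ClusterModel2", function(x) x@featureF)
#' @rdname accessors
setMethod("nullMean", "NullDistribution", function(x) x@nullMean)
#' @rdname accessors
setMethod("nullSd", "NullDistribution", function(x) x@nullSd)
#' @rdname accessors
setMethod("nullDistances", "NullDistribution", function(x) x@distances)

setMethod("show", "CohortSpec", function(object) {
  cat("CohortSpec:", object@nSubjects, "subjects, grid",
      paste(object@gridShape, collapse = "x"), "voxels of",
      paste(object@voxelSize, collapse = "x"), "mm\n")
  cat("  mean lesions/subject:", object@meanLesionsPerSubject,
      "| class-2 fraction:", object@class2Fraction, "\n")
  cat("  lesion size range (voxels):",
      paste(object@lesionSizeRange, collapse = "-"), "\n")
  cat("  class locations (fspgr/se/flair):\n")
  print(object@lesionClassLocation)
  cat("  effect sizes:", paste(names(object@effectSizes),
      sprintf("%.2f", object@effectSizes), sep = "=", collapse = ", "), "\n")
  cat("  master seed:", object@masterSeed, "\n")
})

setMethod("show", "SubjectPhantom", function(object) {
  cat("SubjectPhantom", object@subjectId, "- grid",
      paste(dim(object@lesionLabels), collapse = "x"), "voxels,",
      nrow(object@truth), "lesions\n")
})

setMethod("show", "TissueMedians", function(object) {
  cat("TissueMedians for subject", object@subjectId, "\n")
  print(round(object@medians, 2))
})

setMethod("show", "ClusterModel2", function(object) {
  cat("ClusterModel2:", length(object@labels), "lesions ->",
      paste(object@sizes, collapse = " / "),
      sprintf("(converged: %s, iterations: %d)\n",
              object@converged, object@iterations))
  cat("  centers:\n"); print(round(object@centers, 2))
  cat("  feature F:", paste(names(object@featureF),
      sprintf("%.2f", object@featureF), sep = "=", collapse = ", "), "\n")
})

setMethod("show", "NullDistribution", function(object) {
  cat(sprintf("NullDistribution (%s, %s): %d distances, mean %.4f, sd %.4g\n",
              object@subjectId, object@sequence, length(object@distances),
              object@nullMean, object@nullSd))
})
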