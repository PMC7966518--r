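#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Construct a CohortSpec with study-condition defaults
#'
#' The defaults emulate the cohort the analysis is calibrated against: 79
#' relapsing-remitting MS subjects with on average ~8.8 lesions each (~694
#' lesions cohort-wide), split between two intensity classes. Class median
#' locations follow the reported final cluster centers on FSPGR / SE / FLAIR,
#' with spreads chosen so that the two classes are disjoint on FSPGR, close
#' on SE and essentially coincident on FLAIR. Tissue base intensities are
#' chosen to satisfy the T1-weighted ordering CSF < GM < lesions < WM on
#' FSPGR and SE, and to make class-2 lesions sit near the WM intensity on SE
#' (so they do not stand out there), with hyperintense lesions on FLAIR.
#'
#' @param nSubjects number of subjects (default 79).
#' @param gridShape voxels per axis (default 96 x 96 x 64; a scaled-down
#'   head-size grid that keeps a full cohort tractable in memory).
#' @param voxelSize mm per axis (default 1 mm isotropic, so voxel counts and
#'   mm^3 volumes coincide).
#' @param tissueIntensities 3 x 3 matrix of tissue intensity locations,
#'   rows fspgr/se/flair, columns wm/gm/csf.
#' @param lesionClassLocation 2 x 3 matrix of class median locations
#'   (rows = classes, columns = sequences).
#' @param lesionClassSpread 2 x 3 matrix of class median spreads.
#' @param meanLesionsPerSubject Poisson rate of lesions per subject
#'   (default 694 / 79).
#' @param lesionSizeRange voxel-count range of the log-uniform lesion size
#'   distribution; straddles the 100-voxel analysis filter.
#' @param class2Fraction probability a lesion belongs to class 2
#'   (default 470 / 694).
#' @param effectSizes named target Spearman correlations: class-2 lesion
#'   count with EDSS and disease duration, class-2 lesion volume with
#'   normalized brain volume.
#' @param noiseFraction per-voxel Gaussian noise sd as a fraction of the
#'   noise-free intensity (default 0.03).
#' @param masterSeed integer master seed.
#' @return A validated [CohortSpec-class] object.
#' @examples
#' spec <- cohortSpec(nSubjects = 2, gridShape = c(48, 48, 32),
#'                    meanLesionsPerSubject = 3)
#' spec
#' @export
cohortSpec <- function(nSubjects = 79L,
                       gridShape = c(96L, 96L, 64L),
                       voxelSize = c(1, 1, 1),
                       tissueIntensities = NULL,
                       lesionClassLocation = NULL,
                       lesionClassSpread = NULL,
                       meanLesionsPerSubject = 694 / 79,
                       lesionSizeRange = c(60, 2000),
                       class2Fraction = 470 / 694,
                       effectSizes = c(edss = 0.30, duration = 0.33,
                                       nbv = -0.51),
                       noiseFraction = 0.03,
                       masterSeed = 20210303L) {
  if (is.null(tissueIntensities)) {
    tissueIntensities <- rbind(
      fspgr = c(wm = 4800, gm = 3000, csf = 800),
      se    = c(wm = 2000, gm = 1400, csf = 600),
      flair = c(wm = 2200, gm = 2400, csf = 300))
  }
  if (is.null(lesionClassLocation)) {
    lesionClassLocation <- rbind(
      class1 = c(fspgr = 3525.20, se = 1701.23, flair = 2575.23),
      class2 = c(fspgr = 4280.42, se = 1887.77, flair = 2555.67))
  }
  if (is.null(lesionClassSpread)) {
    lesionClassSpread <- rbind(
      class1 = c(fspgr = 150, se = 150, flair = 220),
      class2 = c(fspgr = 110, se = 65, flair = 240))
  }
  obj <- new("CohortSpec",
    nSubjects = as.integer(nSubjects),
    gridShape = as.integer(gridShape),
    voxelSize = as.numeric(voxelSize),
    tissueIntensities = tissueIntensities,
    lesionClassLocation = lesionClassLocation,
    lesionClassSpread = lesionClassSpread,
    meanLesionsPerSubject = meanLesionsPerSubject,
    lesionSizeRange = as.numeric(lesionSizeRange),
    class2Fraction = class2Fraction,
    effectSizes = effectSizes,
    noiseFraction = noiseFraction,
    masterSeed = as.integer(masterSeed))
  validObject(obj)
  obj
}

# Truncated-normal sampler via inverse-CDF (vectorized, deterministic given
# the RNG state).
.rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  a <- stats::pnorm((lower - mean) / sd)
  b <- stats::pnorm((upper - mean) / sd)
  u <- stats::runif(n, a, b)
  mean + sd * stats::qnorm(u)
}

# Draw the statistical skeleton of one subject: lesion count, classes,
# sizes/shapes and per-sequence sampled medians. Consumes the RNG stream
# first, so a truth-only draw matches the full render exactly.
.sampleSubjectTruth <- function(spec) {
  nLes <- stats::rpois(1L, spec@meanLesionsPerSubject)
  if (nLes == 0L) {
    return(data.frame(lesion_id = integer(0), class = integer(0),
                      voxel_count = integer(0),
                      radius_x = numeric(0), radius_y = numeric(0),
                      radius_z = numeric(0),
                      median_fspgr = numeric(0), median_se = numeric(0),
                      median_flair = numeric(0)))
  }
  cls <- stats::rbinom(nLes, 1L, spec@class2Fraction) + 1L
  sz <- exp(stats::runif(nLes, log(spec@lesionSizeRange[1]),
                         log(spec@lesionSizeRange[2])))
  asp <- matrix(exp(stats::runif(3L * nLes, log(0.7), log(1.4))),
                nLes, 3L)
  asp <- asp / exp(rowMeans(log(asp)))  # normalize product to 1
  ti <- spec@tissueIntensities
  med <- matrix(NA_real_, nLes, 3L, dimnames = list(NULL, .SEQUENCES))
  for (s in .SEQUENCES) {
    lower <- if (s == "flair") ti[s, "wm"] else ti[s, "gm"]
    upper <- if (s == "flair") Inf else ti[s, "wm"]
    med[, s] <- .rtruncnorm(nLes,
                            mean = spec@lesionClassLocation[cls, s],
                            sd = spec@lesionClassSpread[cls, s],
                            lower = lower, upper = upper)
  }
  radii <- t(vapply(seq_len(nLes),
                    function(i) .radiiForCount(sz[i], asp[i, ]),
                    numeric(3)))
  counts <- vapply(seq_len(nLes),
                   function(i) nrow(.ellipsoidOffsets(radii[i, ])),
                   integer(1))
  out <- data.frame(lesion_id = seq_len(nLes), class = cls,
                    voxel_count = counts,
                    radius_x = radii[, 1], radius_y = radii[, 2],
                    radius_z = radii[, 3],
                    median_fspgr = med[, "fspgr"], median_se = med[, "se"],
                    median_flair = med[, "flair"])
  rownames(out) <- NULL
  out
}

# Geometry of the phantom head: normalized radial coordinate and smooth
# partial-volume maps for three concentric compartments (WM core, GM shell,
# CSF shell).
.phantomGeometry <- function(gridShape) {
  semi <- pmax(gridShape / 2 - 4, 3)
  ctr <- (gridShape + 1) / 2
  ax <- ((seq_len(gridShape[1]) - ctr[1]) / semi[1])^2
  ay <- ((seq_len(gridShape[2]) - ctr[2]) / semi[2])^2
  az <- ((seq_len(gridShape[3]) - ctr[3]) / semi[3])^2
  r2 <- outer(outer(ax, ay, "+"), az, "+")
  r <- sqrt(r2)
  w <- 0.05
  wm <- .clamp01((0.62 - r) / w + 0.5)
  gmOuter <- .clamp01((0.82 - r) / w + 0.5)
  csfOuter <- .clamp01((1.0 - r) / w + 0.5)
  list(wm = wm, gm = gmOuter - wm, csf = csfOuter - gmOuter,
       brain = csfOuter)
}

#' Generate one synthetic subject
#'
#' Builds a miniature head phantom (concentric WM / GM / CSF compartments
#' with smooth partial-volume transitions), places lesions as axis-aligned
#' ellipsoids fully inside WM-dominant voxels without overlap, and renders
#' the three co-registered intensity volumes with multiplicative-fraction
#' Gaussian noise. Each lesion's voxels are centred on its class-specific
#' sampled median on every sequence.
#'
#' @param spec a [CohortSpec-class].
#' @param subjectSeed integer seed for this subject (see
#'   [generateCohort()] for the derivation from the master seed).
#' @param subjectId character identifier (default derived from the seed).
#' @return A [SubjectPhantom-class] object.
#' @examples
#' spec <- cohortSpec(nSubjects = 1, gridShape = c(48, 48, 32),
#'                    meanLesionsPerSubject = 3, lesionSizeRange = c(60, 400))
#' subj <- generateSubject(spec, subjectSeed = 1L)
#' subj
#' @export
generateSubject <- function(spec, subjectSeed, subjectId = NULL) {
  validObject(spec)
  if (is.null(subjectId)) subjectId <- sprintf("S%06d", subjectSeed %% 1000000L)
  set.seed(as.integer(subjectSeed))
  truth <- .sampleSubjectTruth(spec)
  d <- spec@gridShape
  geo <- .phantomGeometry(d)
  wmDominant <- geo$wm > 0.5
  labels <- array(0L, d)
  nLes <- nrow(truth)
  if (nLes > 0L) {
    wmIdx <- which(wmDominant)
    if (length(wmIdx) == 0L)
      stop("phantom grid too small: no WM-dominant voxels")
    wmCoord <- arrayInd(wmIdx, d)
    # place large lesions first to ease packing
    for (i in order(truth$voxel_count, decreasing = TRUE)) {
      off <- .ellipsoidOffsets(c(truth$radius_x[i], truth$radius_y[i],
                                 truth$radius_z[i]))
      fits <- function(ctr) {
        vox <- sweep(off, 2, ctr, "+")
        if (any(vox < 1L) || any(vox[, 1] > d[1]) || any(vox[, 2] > d[2]) ||
            any(vox[, 3] > d[3])) return(NULL)
        lin <- vox[, 1] + d[1] * (vox[, 2] - 1L) + d[1] * d[2] * (vox[, 3] - 1L)
        if (all(wmDominant[lin]) && all(labels[lin] == 0L)) lin else NULL
      }
      placed <- FALSE
      for (attempt in seq_len(300L)) {
        lin <- fits(wmCoord[sample.int(nrow(wmCoord), 1L), ])
        if (!is.null(lin)) {
          labels[lin] <- truth$lesion_id[i]
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        # crowded grid: exhaustive scan of WM centres in random order
        for (ci in sample.int(nrow(wmCoord))) {
          lin <- fits(wmCoord[ci, ])
          if (!is.null(lin)) {
            labels[lin] <- truth$lesion_id[i]
            placed <- TRUE
            break
          }
        }
      }
      if (!placed)
        stop(sprintf(
          "could not place lesion %d (%d voxels) after bounded retries; grid too small for the requested lesions",
          truth$lesion_id[i], truth$voxel_count[i]))
    }
  }
  ti <- spec@tissueIntensities
  vols <- list()
  n <- prod(d)
  for (s in .SEQUENCES) {
    base <- geo$wm * ti[s, "wm"] + geo$gm * ti[s, "gm"] +
      geo$csf * ti[s, "csf"] + (1 - geo$brain) * 50
    vol <- base + stats::rnorm(n, 0, spec@noiseFraction * pmax(base, 1))
    vols[[s]] <- array(vol, d)
  }
  if (nLes > 0L) {
    for (i in seq_len(nLes)) {
      lin <- which(labels == truth$lesion_id[i])
      for (s in .SEQUENCES) {
        m <- truth[[paste0("median_", s)]][i]
        vols[[s]][lin] <- stats::rnorm(length(lin), m, spec@noiseFraction * m)
      }
    }
  }
  new("SubjectPhantom",
      subjectId = subjectId,
      volumes = vols,
      lesionLabels = labels,
      tissueMaps = list(wm = geo$wm, gm = geo$gm, csf = geo$csf),
      voxelSize = spec@voxelSize,
      truth = truth)
}

#' Per-subject seeds derived from a master seed
#'
#' Deterministic counter scheme: seed_i = (master + 99991 * i) mod
#' (2^31 - 19), so subjects are reproducible independently of one another.
#'
#' @param spec a [CohortSpec-class].
#' @param i subject index (1-based); i = 0 is reserved for the clinical
#'   covariate table.
#' @return Integer seed(s).
#' @export
subjectSeeds <- function(spec, i = seq_len(spec@nSubjects)) {
  .deriveSeed(spec@masterSeed, i)
}

#' Draw the cohort's lesion truth table without rendering volumes
#'
#' Produces exactly the per-lesion truth (class, voxel count, sampled
#' medians) that [generateCohort()] would embed in its subjects, by
#' replaying each subject's seed up to the point where voxel rendering
#' starts. Useful for statistical calibration studies where the voxel grids
#' themselves are not needed.
#'
#' @param spec a [CohortSpec-class].
#' @return data.frame with one row per lesion and a subject_id column.
#' @export
simulateCohortTruth <- function(spec) {
  validObject(spec)
  out <- vector("list", spec@nSubjects)
  seeds <- subjectSeeds(spec)
  for (i in seq_len(spec@nSubjects)) {
    set.seed(seeds[i])
    tr <- .sampleSubjectTruth(spec)
    if (nrow(tr)) tr$subject_id <- sprintf("S%03d", i)
    else tr$subject_id <- character(0)
    out[[i]] <- tr
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df[, c("subject_id", setdiff(names(df), "subject_id"))]
}

#' Generate a full synthetic cohort
#'
#' Generates \code{nSubjects} phantoms plus a clinical covariate table whose
#' associations with class-2 lesion burden follow the spec's effect sizes.
#' Fully reproducible from the master seed: the same spec yields
#' bit-identical volumes and tables on every run.
#'
#' @param spec a [CohortSpec-class].
#' @return A list with elements \code{subjects} (list of
#'   [SubjectPhantom-class]), \code{clinical} (data.frame) and \code{truth}
#'   (combined per-lesion truth with subject ids). For large cohorts consider
#'   the streaming analysis in [analyzeCohort()] instead, which does not
#'   hold all volumes in memory at once.
#' @examples
#' spec <- cohortSpec(nSubjects = 2, gridShape = c(48, 48, 32),
#'                    meanLesionsPerSubject = 2, lesionSizeRange = c(60, 300))
#' coh <- generateCohort(spec)
#' length(coh$subjects); nrow(coh$clinical)
#' @export
generateCohort <- function(spec) {
  validObject(spec)
  seeds <- subjectSeeds(spec)
  subjects <- vector("list", spec@nSubjects)
  for (i in seq_len(spec@nSubjects)) {
    subjects[[i]] <- generateSubject(spec, seeds[i],
                                     subjectId = sprintf("S%03d", i))
  }
  truthList <- lapply(subjects, lesionTruth)
  names(truthList) <- vapply(subjects, subjectId, character(1))
  clinical <- generateClinicalTable(truthList, spec)
  truth <- do.call(rbind, lapply(names(truthList), function(id) {
    tr <- truthList[[id]]
    if (nrow(tr)) tr$subject_id <- id else tr$subject_id <- character(0)
    tr
  }))
  rownames(truth) <- NULL
  list(subjects = subjects, clinical = clinical,
       truth = truth[, c("subject_id", setdiff(names(truth), "subject_id"))])
}

#' Write a cohort to disk as NIfTI volumes and CSV tables
#'
#' Each subject is written as seven gzipped NIfTI-1 volumes (three
#' sequences, one lesion label grid, three partial-volume maps) with the
#' voxel size recorded in the header, plus a per-subject truth CSV. The
#' clinical table is written as CSV and a JSON manifest records every file
#' with its md5 checksum.
#'
#' @param cohort a list as returned by [generateCohort()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest as a list (also written to
#'   \code{manifest.json}).
#' @export
writeFixtures <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  files <- character(0)
  for (subj in cohort$subjects) {
    sdir <- file.path(dir, subjectId(subj))
    dir.create(sdir, showWarnings = FALSE)
    grids <- c(volumes(subj),
               list(lesion_labels = lesionLabels(subj)),
               stats::setNames(tissueMaps(subj),
                               paste0("pv_", names(tissueMaps(subj)))))
    for (nm in names(grids)) {
      img <- RNifti::asNifti(grids[[nm]])
      RNifti::pixdim(img) <- voxelSize(subj)
      p <- file.path(sdir, paste0(nm, ".nii.gz"))
      RNifti::writeNifti(img, p)
      files <- c(files, p)
    }
    tp <- file.path(sdir, "truth.csv")
    utils::write.csv(lesionTruth(subj), tp, row.names = FALSE)
    files <- c(files, tp)
  }
  cp <- file.path(dir, "clinical.csv")
  utils::write.csv(cohort$clinical, cp, row.names = FALSE)
  files <- c(files, cp)
  manifest <- list(n_subjects = length(cohort$subjects),
                   files = .fileChecksums(files, root = dir))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Read a subject phantom back from a fixture directory
#'
#' @param dir cohort directory written by [writeFixtures()].
#' @param id subject identifier (sub-directory name).
#' @return A [SubjectPhantom-class] object.
#' @export
readSubjectPhantom <- function(dir, id) {
  sdir <- file.path(dir, id)
  rd <- function(nm) {
    img <- RNifti::readNifti(file.path(sdir, paste0(nm, ".nii.gz")))
    array(as.numeric(img), dim(img))
  }
  labels <- rd("lesion_labels")
  storage.mode(labels) <- "integer"
  img <- RNifti::readNifti(file.path(sdir, "fspgr.nii.gz"))
  truth <- utils::read.csv(file.path(sdir, "truth.csv"))
  new("SubjectPhantom",
      subjectId = id,
      volumes = list(fspgr = rd("fspgr"), se = rd("se"), flair = rd("flair")),
      lesionLabels = labels,
      tissueMaps = list(wm = rd("pv_wm"), gm = rd("pv_gm"),
                        csf = rd("pv_csf")),
      voxelSize = RNifti::pixdim(img)[1:3],
      truth = truth)
}
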