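#' @include AllClasses.R phantom.R clinical.R preprocess.R features.R cluster.R slz.R clinstats.R
NULL

#' Run the full lesion-typing analysis on a synthetic cohort, in memory
#'
#' Streams the cohort subject by subject (volumes are generated, analyzed
#' and discarded, so a full-size cohort never resides in memory at once):
#' optionally learns cohort landmark maps and standardizes intensities, then
#' per subject conditions the lesion labelling (size filter), computes
#' reference-tissue medians with lesions excluded from WM, extracts
#' per-lesion median and ratio features, builds the bootstrap WM null and
#' standardized lesion distances (Z) per sequence. Cohort-level steps
#' follow: two-cluster K-means on the pooled medians, per-feature influence
#' F, Z-threshold exceedance percentages per cluster and sequence, burden
#' summaries, the Wilcoxon/Mann-Whitney contrasts of the standardized
#' intensities, and Bonferroni-corrected Spearman correlations of cluster
#' burden with the generated clinical covariates.
#'
#' @param spec a [CohortSpec-class].
#' @param nullSamples bootstrap references per subject and sequence
#'   (default 5000).
#' @param zThreshold exceedance threshold on the standardized lesion
#'   distance (default 2.3).
#' @param minLesionVoxels lesion size filter: only components strictly
#'   larger than this survive (default 100).
#' @param standardize apply cohort landmark standardization before feature
#'   extraction (default TRUE).
#' @param maxIterations K-means iteration cap (default 10).
#' @return A list with elements \code{features} (the lesion table with
#'   ratios, z scores, cluster and truth labels), \code{model}
#'   ([ClusterModel2-class]), \code{summary}, \code{exceedance},
#'   \code{burden}, \code{clinical}, \code{correlations}, \code{tests},
#'   \code{tissueMedians} (per-subject matrix list), \code{labelAgreement}
#'   (fraction of lesions whose cluster matches the generating class) and
#'   \code{nLesionsGenerated}.
#' @export
analyzeCohort <- function(spec, nullSamples = 5000L, zThreshold = 2.3,
                          minLesionVoxels = 100L, standardize = TRUE,
                          maxIterations = 10L) {
  validObject(spec)
  seeds <- subjectSeeds(spec)
  ids <- sprintf("S%03d", seq_len(spec@nSubjects))
  landmarkMaps <- NULL
  if (standardize) {
    pct <- seq(10, 90, by = 10)
    acc <- lapply(.SEQUENCES, function(s) NULL)
    names(acc) <- .SEQUENCES
    for (i in seq_len(spec@nSubjects)) {
      subj <- generateSubject(spec, seeds[i], subjectId = ids[i])
      for (s in .SEQUENCES) {
        q <- stats::quantile(as.vector(volumes(subj)[[s]]), pct / 100,
                             names = FALSE)
        acc[[s]] <- if (is.null(acc[[s]])) q else acc[[s]] + q
      }
    }
    landmarkMaps <- lapply(acc, function(a)
      list(percentiles = pct, landmarks = a / spec@nSubjects))
  }
  featList <- vector("list", spec@nSubjects)
  truthList <- vector("list", spec@nSubjects)
  tmList <- vector("list", spec@nSubjects)
  names(truthList) <- ids
  names(tmList) <- ids
  nGenerated <- 0L
  for (i in seq_len(spec@nSubjects)) {
    subj <- generateSubject(spec, seeds[i], subjectId = ids[i])
    truthList[[i]] <- lesionTruth(subj)
    nGenerated <- nGenerated + nrow(lesionTruth(subj))
    vols <- volumes(subj)
    if (standardize)
      vols <- lapply(.SEQUENCES, function(s)
        standardizeIntensities(vols[[s]], landmarkMaps[[s]]))
    names(vols) <- .SEQUENCES
    fullMask <- lesionLabels(subj) > 0L
    filtered <- labelAndFilterLesions(lesionLabels(subj), minLesionVoxels)
    kept <- attr(filtered, "keptLabels")
    tm <- tissueMedians(vols, tissueMaps(subj), fullMask,
                        subjectId = ids[i])
    tmList[[i]] <- tm@medians
    feat <- extractSubjectFeatures(vols, filtered, tm, voxelSize(subj),
                                   ids[i])
    if (nrow(feat)) {
      feat$truth_class <- lesionTruth(subj)$class[kept]
      for (si in seq_along(.SEQUENCES)) {
        s <- .SEQUENCES[si]
        null <- buildNull(wmIntensities(tm, s), nSamples = nullSamples,
                          seed = .deriveSeed(seeds[i], si),
                          subjectId = ids[i], sequence = s)
        zs <- lesionZScores(feat[[paste0("median_", s)]],
                            wmIntensities(tm, s), null)
        feat[[paste0("z_", s)]] <- zs$z
      }
    }
    featList[[i]] <- feat
  }
  extraCols <- c("truth_class", paste0("z_", .SEQUENCES))
  features <- buildFeatureTable(lapply(featList, function(df)
    if (nrow(df)) df[, .featureTableColumns()] else df))
  extras <- do.call(rbind, lapply(featList, function(df)
    if (nrow(df)) df[order(df$subject_id, df$lesion_id), extraCols,
                     drop = FALSE]
    else NULL))
  if (!is.null(extras)) features[, extraCols] <- extras
  if (nrow(features) < 2L)
    stop("fewer than 2 lesions survived the size filter; cannot cluster")
  model <- fitKMeans2(features, maxIterations = maxIterations)
  features$cluster_label <- clusterLabels(model)
  clinical <- generateClinicalTable(truthList, spec,
                                    minLesionVoxels = minLesionVoxels)
  burden <- burdenSummary(features, subjectIds = ids)
  correlations <- spearmanWithCorrection(burden, clinical)
  tests <- list(
    wilcoxon_wm_fspgr = wilcoxonVsUnity(features$ratio_wm_fspgr),
    wilcoxon_wm_se = wilcoxonVsUnity(features$ratio_wm_se),
    wilcoxon_gm_fspgr = wilcoxonVsUnity(features$ratio_gm_fspgr),
    wilcoxon_gm_se = wilcoxonVsUnity(features$ratio_gm_se),
    wilcoxon_csf_fspgr = wilcoxonVsUnity(features$ratio_csf_fspgr),
    wilcoxon_csf_se = wilcoxonVsUnity(features$ratio_csf_se),
    mann_whitney_se_vs_fspgr = mannWhitneyU(features$ratio_wm_se,
                                            features$ratio_wm_fspgr))
  list(features = features,
       model = model,
       summary = clusterSummary(model, features),
       exceedance = exceedancePercentages(features, zThreshold),
       burden = burden,
       clinical = clinical,
       correlations = correlations,
       tests = tests,
       tissueMedians = tmList,
       labelAgreement = mean(features$cluster_label == features$truth_class),
       nLesionsGenerated = nGenerated)
}

.pipelineSpec <- function(config) {
  specArgs <- config[intersect(names(config),
                               names(formals(cohortSpec)))]
  do.call(cohortSpec, specArgs)
}

.writeStage <- function(state, stage, files) {
  state$stages[[stage]] <- list(outputs = .fileChecksums(files,
                                                         root = state$outDir))
  state
}

#' Run the staged, file-based analysis pipeline
#'
#' Orchestrates simulate -> preprocess -> extract -> cluster -> slz ->
#' correlate with file-based contracts between stages (NIfTI volumes, CSV
#' tables, JSON reports), and writes a reproducibility manifest recording
#' the configuration, the seed, and the md5 checksum of every artifact. A
#' stage failure aborts with the stage name and leaves an
#' \code{INCOMPLETE} marker next to the partial outputs. Re-running with an
#' identical configuration reproduces identical artifacts.
#'
#' @param config named list of options: any [cohortSpec()] argument plus
#'   \code{nullSamples}, \code{zThreshold}, \code{minLesionVoxels},
#'   \code{standardize}. May also be a path to a JSON file holding the list.
#' @param outDir output directory.
#' @return Invisibly, the manifest list (also written as
#'   \code{manifest.json}).
#' @export
runPipeline <- function(config, outDir) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  spec <- .pipelineSpec(config)
  nullSamples <- config$nullSamples %||% 5000L
  zThreshold <- config$zThreshold %||% 2.3
  minLesionVoxels <- config$minLesionVoxels %||% 100L
  standardize <- config$standardize %||% TRUE
  state <- list(outDir = outDir, stages = list())
  marker <- file.path(outDir, "INCOMPLETE")
  file.create(marker)
  stageEnv <- new.env()
  runStage <- function(name, fun) {
    files <- tryCatch(fun(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    state <<- .writeStage(state, name, files)
  }
  runStage("simulate", function() {
    d <- file.path(outDir, "simulate")
    cohort <- generateCohort(spec)
    writeFixtures(cohort, d)
    stageEnv$cohort <- cohort
    list.files(d, recursive = TRUE, full.names = TRUE)
  })
  runStage("preprocess", function() {
    d <- file.path(outDir, "preprocess")
    dir.create(d, showWarnings = FALSE)
    cohort <- stageEnv$cohort
    landmarkMaps <- NULL
    if (standardize) {
      landmarkMaps <- lapply(.SEQUENCES, function(s)
        learnLandmarks(lapply(cohort$subjects, function(x) volumes(x)[[s]])))
      names(landmarkMaps) <- .SEQUENCES
    }
    stageEnv$landmarkMaps <- landmarkMaps
    stageEnv$prep <- list()
    files <- character(0)
    if (standardize) {
      lp <- file.path(d, "landmarks.json")
      jsonlite::write_json(landmarkMaps, lp, auto_unbox = TRUE, digits = NA)
      files <- c(files, lp)
    }
    for (subj in cohort$subjects) {
      id <- subjectId(subj)
      vols <- volumes(subj)
      if (standardize)
        vols <- stats::setNames(lapply(.SEQUENCES, function(s)
          standardizeIntensities(vols[[s]], landmarkMaps[[s]])), .SEQUENCES)
      filtered <- labelAndFilterLesions(lesionLabels(subj), minLesionVoxels)
      tm <- tissueMedians(vols, tissueMaps(subj), lesionLabels(subj) > 0L,
                          subjectId = id)
      stageEnv$prep[[id]] <- list(vols = vols, filtered = filtered, tm = tm)
      rp <- file.path(d, paste0("report_", id, ".json"))
      jsonlite::write_json(list(
        subject_id = id,
        lesions_before_filter = nrow(lesionTruth(subj)),
        lesions_after_filter = max(filtered),
        tissue_medians = as.data.frame(tm@medians)), rp,
        auto_unbox = TRUE, digits = NA)
      files <- c(files, rp)
    }
    files
  })
  runStage("extract", function() {
    d <- file.path(outDir, "extract")
    dir.create(d, showWarnings = FALSE)
    cohort <- stageEnv$cohort
    featList <- lapply(cohort$subjects, function(subj) {
      pr <- stageEnv$prep[[subjectId(subj)]]
      extractSubjectFeatures(pr$vols, pr$filtered, pr$tm,
                             voxelSize(subj), subjectId(subj))
    })
    features <- buildFeatureTable(featList)
    stageEnv$features <- features
    fp <- file.path(d, "features.csv")
    utils::write.csv(features, fp, row.names = FALSE)
    fp
  })
  runStage("cluster", function() {
    d <- file.path(outDir, "cluster")
    dir.create(d, showWarnings = FALSE)
    model <- fitKMeans2(stageEnv$features)
    stageEnv$features$cluster_label <- clusterLabels(model)
    stageEnv$model <- model
    sp <- file.path(d, "cluster_summary.json")
    jsonlite::write_json(list(
      centers = as.data.frame(centers(model)),
      sizes = clusterSizes(model),
      feature_F = as.list(featureF(model)),
      iterations = model@iterations), sp, auto_unbox = TRUE, digits = NA)
    lp <- file.path(d, "labeled_features.csv")
    utils::write.csv(stageEnv$features, lp, row.names = FALSE)
    c(sp, lp)
  })
  runStage("slz", function() {
    d <- file.path(outDir, "slz")
    dir.create(d, showWarnings = FALSE)
    cohort <- stageEnv$cohort
    features <- stageEnv$features
    for (s in .SEQUENCES) features[[paste0("z_", s)]] <- NA_real_
    for (subj in cohort$subjects) {
      id <- subjectId(subj)
      pr <- stageEnv$prep[[id]]
      sel <- which(features$subject_id == id)
      if (!length(sel)) next
      for (si in seq_along(.SEQUENCES)) {
        s <- .SEQUENCES[si]
        null <- buildNull(wmIntensities(pr$tm, s), nSamples = nullSamples,
                          seed = .deriveSeed(subjectSeeds(spec,
                            match(id, sprintf("S%03d", seq_len(spec@nSubjects)))), si),
                          subjectId = id, sequence = s)
        zs <- lesionZScores(features[[paste0("median_", s)]][sel],
                            wmIntensities(pr$tm, s), null)
        features[[paste0("z_", s)]][sel] <- zs$z
      }
    }
    stageEnv$features <- features
    ex <- exceedancePercentages(features, zThreshold)
    ep <- file.path(d, "exceedance.json")
    jsonlite::write_json(ex, ep, auto_unbox = TRUE, digits = NA)
    zp <- file.path(d, "features_z.csv")
    utils::write.csv(features, zp, row.names = FALSE)
    c(ep, zp)
  })
  runStage("correlate", function() {
    d <- file.path(outDir, "correlate")
    dir.create(d, showWarnings = FALSE)
    cohort <- stageEnv$cohort
    ids <- vapply(cohort$subjects, subjectId, character(1))
    burden <- burdenSummary(stageEnv$features, subjectIds = ids)
    cors <- spearmanWithCorrection(burden, cohort$clinical)
    cp <- file.path(d, "correlations.csv")
    utils::write.csv(cors, cp, row.names = FALSE)
    tryTest <- function(expr) tryCatch(unclass(expr), error = function(e)
      list(error = conditionMessage(e)))
    tests <- list(
      wilcoxon_wm_fspgr = tryTest(wilcoxonVsUnity(stageEnv$features$ratio_wm_fspgr)),
      wilcoxon_wm_se = tryTest(wilcoxonVsUnity(stageEnv$features$ratio_wm_se)),
      mann_whitney_se_vs_fspgr = tryTest(mannWhitneyU(
        stageEnv$features$ratio_wm_se, stageEnv$features$ratio_wm_fspgr)))
    tp <- file.path(d, "tests.json")
    jsonlite::write_json(tests, tp, auto_unbox = TRUE, digits = NA)
    c(cp, tp)
  })
  cfgFile <- tempfile(fileext = ".json")
  jsonlite::write_json(config, cfgFile, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    seed = spec@masterSeed,
    config = config,
    config_md5 = unname(tools::md5sum(cfgFile)),
    r_version = as.character(getRversion()),
    stages = state$stages)
  unlink(cfgFile)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  unlink(marker)
  invisible(manifest)
}

#' Verify the artifacts of a pipeline run against its manifest
#'
#' Recomputes the md5 checksum of every file listed in the run manifest and
#' reports mismatches (corrupted or missing intermediates).
#'
#' @param outDir directory of a completed [runPipeline()] run.
#' @return data.frame with columns stage, file, status ("ok", "mismatch" or
#'   "missing").
#' @export
verifyRunManifest <- function(outDir) {
  mf <- jsonlite::read_json(file.path(outDir, "manifest.json"))
  rows <- list()
  for (stage in names(mf$stages)) {
    outs <- mf$stages[[stage]]$outputs
    for (f in names(outs)) {
      path <- file.path(outDir, f)
      status <- if (!file.exists(path)) "missing"
        else if (unname(tools::md5sum(path)) == outs[[f]]) "ok"
        else "mismatch"
      rows[[length(rows) + 1L]] <- data.frame(stage = stage, file = f,
                                              status = status)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
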