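test_that("cohort generation is bit-identical under a fixed master seed", {
  spec <- smallSpec(nSubjects = 2L)
  c1 <- generateCohort(spec)
  c2 <- generateCohort(spec)
  expect_identical(lapply(c1$subjects, volumes),
                   lapply(c2$subjects, volumes))
  expect_identical(lapply(c1$subjects, lesionLabels),
                   lapply(c2$subjects, lesionLabels))
  expect_identical(c1$clinical, c2$clinical)
  expect_identical(c1$truth, c2$truth)
})

test_that("a zero lesion rate yields empty labellings and empty truth", {
  spec <- smallSpec(nSubjects = 2L, meanLesionsPerSubject = 0)
  coh <- generateCohort(spec)
  for (subj in coh$subjects) {
    expect_identical(max(lesionLabels(subj)), 0L)
    expect_identical(nrow(lesionTruth(subj)), 0L)
  }
  expect_identical(nrow(coh$clinical), 2L)
})

test_that("truth-only simulation replays exactly what full generation embeds", {
  spec <- smallSpec(nSubjects = 3L)
  coh <- generateCohort(spec)
  truth <- simulateCohortTruth(spec)
  expect_equal(truth, coh$truth)
})

test_that("the default lesion rate yields a cohort-wide total near 694", {
  spec <- cohortSpec()  # 79 subjects, 694/79 lesions each on average
  truth <- simulateCohortTruth(spec)
  # Poisson(694) total: +-3 sd is about +-79
  expect_gt(nrow(truth), 694 - 80)
  expect_lt(nrow(truth), 694 + 80)
})

test_that("tissue and lesion intensities obey the T1 ordering CSF < GM < lesions < WM", {
  subj <- smallSubject(seed = 7L)
  tm <- tissueMedians(volumes(subj), tissueMaps(subj),
                      lesionLabels(subj) > 0L)
  filtered <- labelAndFilterLesions(lesionLabels(subj), 0L)
  med <- lesionMedians(volumes(subj), filtered)
  for (s in c("fspgr", "se")) {
    expect_lt(tissueMedian(tm, s, "csf"), tissueMedian(tm, s, "gm"))
    lm <- med[[paste0("median_", s)]]
    expect_true(all(lm > tissueMedian(tm, s, "gm")))
    expect_true(all(lm < tissueMedian(tm, s, "wm")))
  }
  # FLAIR lesions are hyperintense relative to WM
  expect_true(all(med$median_flair > tissueMedian(tm, "flair", "wm")))
})

test_that("between-class separation is ordered FSPGR > SE > FLAIR", {
  spec <- cohortSpec(masterSeed = 404L)
  truth <- simulateCohortTruth(spec)
  gap <- vapply(c("fspgr", "se", "flair"), function(s) {
    m <- truth[[paste0("median_", s)]]
    pooled <- sqrt(mean(tapply(m, truth$class, stats::var)))
    abs(diff(tapply(m, truth$class, mean))) / pooled
  }, numeric(1))
  expect_gt(gap[["fspgr"]], gap[["se"]])
  expect_gt(gap[["se"]], gap[["flair"]])
})

test_that("a unit-radius ellipsoid lesion cannot exceed its 3x3x3 bounding box", {
  off <- bhtyper:::.ellipsoidOffsets(c(1, 1, 1))
  expect_lte(nrow(off), 27)
  expect_true(all(abs(off) <= 1))
})

test_that("all lesion voxels lie in WM-dominant voxels and labels are contiguous", {
  subj <- smallSubject(seed = 31L)
  lab <- lesionLabels(subj)
  wmDominant <- tissueMaps(subj)$wm > 0.5
  expect_true(all(wmDominant[lab > 0L]))
  k <- max(lab)
  expect_setequal(setdiff(unique(as.vector(lab)), 0L), seq_len(k))
})

test_that("null effect sizes give near-zero burden/EDSS correlation", {
  spec <- cohortSpec(effectSizes = c(edss = 0, duration = 0, nbv = 0),
                     masterSeed = 606L)
  truth <- simulateCohortTruth(spec)
  truthList <- split(truth, truth$subject_id)
  clinical <- generateClinicalTable(truthList, spec)
  cl2 <- vapply(truthList, function(tr)
    sum(tr$class == 2L & tr$voxel_count > 100L), numeric(1))
  rho <- suppressWarnings(cor(rank(cl2), rank(clinical$edss)))
  expect_lt(abs(rho), 0.3)
})

test_that("invalid specs fail with the offending field named", {
  expect_error(smallSpec(class2Fraction = 1.5), "class2Fraction")
  expect_error(smallSpec(lesionClassSpread = rbind(
    class1 = c(fspgr = 0, se = 1, flair = 1),
    class2 = c(fspgr = 1, se = 1, flair = 1))), "lesionClassSpread")
  # lesion locations outside the GM..WM band on FSPGR
  bad <- rbind(class1 = c(fspgr = 100, se = 1700, flair = 2500),
               class2 = c(fspgr = 4280, se = 1890, flair = 2560))
  expect_error(smallSpec(lesionClassLocation = bad), "lesionClassLocation")
})

test_that("an impossible placement errors after bounded retries", {
  spec <- smallSpec(gridShape = c(16L, 16L, 16L),
                    meanLesionsPerSubject = 6,
                    lesionSizeRange = c(900, 1000))
  expect_error(smallSubject(seed = 1L, spec = spec),
               "grid too small|no WM-dominant")
})

test_that("fixtures round-trip: files, checksums and grid equality", {
  spec <- smallSpec(nSubjects = 1L, masterSeed = 909L)
  coh <- generateCohort(spec)
  dir <- withr::local_tempdir()
  manifest <- writeFixtures(coh, dir)
  id <- subjectId(coh$subjects[[1]])
  niis <- list.files(file.path(dir, id), pattern = "nii.gz$")
  expect_length(niis, 7L)
  expect_true(file.exists(file.path(dir, "clinical.csv")))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- readSubjectPhantom(dir, id)
  expect_equal(volumes(back), volumes(coh$subjects[[1]]), tolerance = 1e-6)
  expect_identical(lesionLabels(back), lesionLabels(coh$subjects[[1]]))
  expect_equal(tissueMaps(back), tissueMaps(coh$subjects[[1]]),
               tolerance = 1e-6)
})

test_that("an empty cohort writes the clinical table only", {
  dir <- withr::local_tempdir()
  manifest <- writeFixtures(list(subjects = list(),
                                 clinical = data.frame(subject_id = character(0))),
                            dir)
  expect_named(manifest$files, "clinical.csv")
})
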