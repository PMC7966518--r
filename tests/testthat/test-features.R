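mkVols <- function(v) list(fspgr = v, se = v, flair = v)

test_that("lesion medians are computed over each lesion's voxels only", {
  v <- array(0, c(10, 1, 1))
  v[1:3] <- c(10, 20, 30); v[5:6] <- c(100, 200)
  lab <- array(0L, c(10, 1, 1)); lab[1:3] <- 1L; lab[5:6] <- 2L
  med <- lesionMedians(mkVols(v), lab)
  expect_equal(med$median_fspgr, c(20, 150))
  expect_equal(med$voxel_count, c(3L, 2L))
  # locality: perturbing lesion 2 leaves lesion 1 unchanged
  v2 <- v; v2[5] <- 999
  med2 <- lesionMedians(mkVols(v2), lab)
  expect_equal(med2$median_fspgr[1], med$median_fspgr[1])
  expect_false(med2$median_fspgr[2] == med$median_fspgr[2])
})

test_that("standardized intensities are lesion median over tissue median", {
  med <- data.frame(lesion_id = 1L, voxel_count = 10L,
                    median_fspgr = 50, median_se = 100, median_flair = 100)
  tm <- new("TissueMedians", subjectId = "s",
            medians = matrix(100, 3, 3,
                             dimnames = list(c("fspgr", "se", "flair"),
                                             c("wm", "gm", "csf"))),
            wmIntensities = list(fspgr = 1, se = 1, flair = 1))
  out <- standardizedIntensities(med, tm)
  expect_equal(out$ratio_wm_fspgr, 0.5)
  expect_equal(out$ratio_wm_se, 1.0)  # equal to the tissue median
  expect_equal(out$ratio_gm_fspgr, 0.5)
})

test_that("standardized intensities are invariant to global intensity scaling", {
  subj <- smallSubject(seed = 17L)
  filtered <- labelAndFilterLesions(lesionLabels(subj), 0L)
  run <- function(scale) {
    vols <- lapply(volumes(subj), function(v) v * scale)
    tm <- tissueMedians(vols, tissueMaps(subj), lesionLabels(subj) > 0L)
    feat <- lesionMedians(vols, filtered)
    standardizedIntensities(feat, tm)
  }
  base <- run(1)
  for (cc in c(0.5, 3.7)) {
    scaled <- run(cc)
    rcols <- grep("^ratio_", names(base), value = TRUE)
    expect_equal(scaled[rcols], base[rcols], tolerance = 1e-9)
  }
})

test_that("phantom lesions sit below WM and above GM/CSF on T1 sequences", {
  subj <- smallSubject(seed = 23L)
  tm <- tissueMedians(volumes(subj), tissueMaps(subj),
                      lesionLabels(subj) > 0L)
  feat <- extractSubjectFeatures(volumes(subj),
                                 labelAndFilterLesions(lesionLabels(subj), 0L),
                                 tm, voxelSize(subj), "S1")
  expect_true(all(feat$ratio_wm_fspgr < 1))
  expect_true(all(feat$ratio_wm_se < 1))
  expect_true(all(feat$ratio_gm_fspgr > 1))
  expect_true(all(feat$ratio_gm_se > 1))
  expect_true(all(feat$ratio_csf_fspgr > 1))
  # volume = voxel count x voxel volume
  expect_equal(feat$volume_mm3,
               feat$voxel_count * prod(voxelSize(subj)))
})

test_that("phantom lesion medians recover the generating sampled medians", {
  subj <- smallSubject(seed = 29L)
  filtered <- labelAndFilterLesions(lesionLabels(subj), 0L)
  med <- lesionMedians(volumes(subj), filtered)
  truth <- lesionTruth(subj)[attr(filtered, "keptLabels"), ]
  # the sample median of N(m, 0.03 m) voxels stays within ~3% of m
  expect_equal(med$median_fspgr, truth$median_fspgr, tolerance = 0.03)
  expect_equal(med$median_se, truth$median_se, tolerance = 0.03)
})

test_that("the cohort feature table is stably ordered with a complete header", {
  rowFor <- function(id, lesion) {
    df <- data.frame(subject_id = id, lesion_id = lesion, voxel_count = 150L,
                     volume_mm3 = 150, median_fspgr = 1, median_se = 1,
                     median_flair = 1)
    for (t in c("wm", "gm", "csf")) for (s in c("fspgr", "se", "flair"))
      df[[paste0("ratio_", t, "_", s)]] <- 1
    df
  }
  tab <- buildFeatureTable(list(rowFor("S2", 1L), rowFor("S1", 2L),
                                rowFor("S1", 1L), rowFor("S2", 2L),
                                rowFor("S2", 3L), rowFor("S1", 3L)))
  expect_identical(nrow(tab), 6L)
  expect_identical(tab$subject_id, c(rep("S1", 3), rep("S2", 3)))
  expect_identical(tab$lesion_id[1:3], 1:3)
  empty <- buildFeatureTable(list())
  expect_identical(nrow(empty), 0L)
  expect_identical(names(empty), names(tab))
  expect_error(buildFeatureTable(list(rowFor("S1", 1L), rowFor("S1", 1L))),
               "duplicate")
})
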