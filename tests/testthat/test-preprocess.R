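test_that("landmarks of a cohort of one equal that volume's own percentiles", {
  set.seed(1)
  v <- array(runif(1000, 0, 100), c(10, 10, 10))
  lm <- learnLandmarks(list(v))
  expect_equal(lm$landmarks,
               unname(quantile(as.vector(v), seq(0.1, 0.9, 0.1))))
  # two identical volumes change nothing
  lm2 <- learnLandmarks(list(v, v))
  expect_equal(lm2$landmarks, lm$landmarks)
})

test_that("cohort landmarks average the per-volume percentiles", {
  v1 <- array(1:100, c(100, 1, 1))
  v2 <- array(seq(2, 200, by = 2), c(100, 1, 1))
  lm <- learnLandmarks(list(v1, v2), percentiles = c(25, 50, 75))
  oracle <- (quantile(1:100, c(.25, .5, .75)) +
               quantile(seq(2, 200, 2), c(.25, .5, .75))) / 2
  expect_equal(lm$landmarks, unname(oracle))
})

test_that("degenerate (constant) volumes are rejected when learning landmarks", {
  expect_error(learnLandmarks(list(array(5, c(4, 4, 4)))), "degenerate")
})

test_that("standardization is the identity on a volume matching the standard scale", {
  set.seed(2)
  v <- array(rnorm(4000, 100, 15), c(20, 20, 10))
  lm <- learnLandmarks(list(v))
  out <- standardizeIntensities(v, lm)
  expect_equal(out, v, tolerance = 1e-12)
})

test_that("a two-landmark map interpolates linearly between landmarks", {
  v <- array(as.numeric(1:101), c(101, 1, 1))
  # own p25 = 26, own p75 = 76; the midpoint 51 must map to 200
  lm <- list(percentiles = c(25, 75), landmarks = c(100, 300))
  out <- standardizeIntensities(v, lm)
  expect_equal(out[51, 1, 1], 200)
  expect_equal(out[26, 1, 1], 100)
  expect_equal(out[76, 1, 1], 300)
  # tails extrapolate linearly with the segment slope (here slope 4)
  expect_equal(out[1, 1, 1], 100 - 25 * 4)
})

test_that("standardization preserves the within-volume rank order", {
  set.seed(3)
  v <- array(rgamma(2000, 3, 0.01), c(20, 10, 10))
  std <- learnLandmarks(list(array(rnorm(2000, 500, 60), c(20, 10, 10))))
  out <- standardizeIntensities(v, std)
  expect_identical(order(as.vector(out)), order(as.vector(v)))
})

test_that("non-monotone landmark maps are rejected", {
  v <- array(runif(64), c(4, 4, 4))
  expect_error(
    standardizeIntensities(v, list(percentiles = c(25, 50, 75),
                                   landmarks = c(10, 5, 20))),
    "not strictly increasing")
})

test_that("resampling onto the identical grid is the identity for binary masks", {
  set.seed(4)
  m <- array(as.numeric(runif(512) > 0.7), c(8, 8, 8))
  out <- resampleAndBinarizeMask(m, c(8, 8, 8))
  expect_identical(as.vector(out), as.integer(m))
  expect_true(all(out %in% c(0L, 1L)))
})

test_that("an interpolated value of exactly 0.5 is retained", {
  m <- array(c(0.4, 0.6), c(2, 1, 1))
  # 3 target voxels of extent 2/3 mm; the middle centre falls exactly
  # between the two source voxels, interpolating to 0.5
  out <- resampleAndBinarizeMask(m, c(3, 1, 1),
                                 sourceVoxelSize = c(1, 1, 1),
                                 targetVoxelSize = c(2 / 3, 1, 1))
  expect_identical(out[2, 1, 1], 1L)
})

test_that("2x upsampling a single voxel stays within trilinear support", {
  m <- array(0, c(4, 4, 4)); m[2, 2, 2] <- 1
  out <- resampleAndBinarizeMask(m, c(8, 8, 8),
                                 sourceVoxelSize = c(1, 1, 1),
                                 targetVoxelSize = c(0.5, 0.5, 0.5))
  expect_lte(sum(out), 8)
  # brute-force trilinear evaluation as the oracle
  oracle <- 0L
  for (i in 1:8) for (j in 1:8) for (k in 1:8) {
    co <- (c(i, j, k) - 0.5) * 0.5 + 0.5
    f <- floor(pmin(pmax(co, 1), 3)); fr <- co - f
    acc <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- prod(ifelse(c(dx, dy, dz) == 1, fr, 1 - fr))
      acc <- acc + w * m[f[1] + dx, f[2] + dy, f[3] + dz]
    }
    if (acc >= 0.5) oracle <- oracle + 1L
  }
  expect_identical(sum(out), oracle)
})

test_that("mismatched fields of view are rejected", {
  m <- array(0.5, c(4, 4, 4))
  expect_error(resampleAndBinarizeMask(m, c(16, 4, 4)), "incompatible")
  expect_error(resampleAndBinarizeMask(array(2, c(2, 2, 2)), c(2, 2, 2)),
               "\\[0, 1\\]")
})

test_that("the size filter keeps components strictly larger than the threshold", {
  lab <- array(0L, c(30, 30, 3))
  lab[1:99] <- 1L          # 99 voxels
  lab[301:400] <- 2L       # 100 voxels
  lab[601:701] <- 3L       # 101 voxels
  out <- labelAndFilterLesions(lab, 100L)
  expect_identical(max(out), 1L)
  expect_identical(attr(out, "keptLabels"), 3L)
  expect_identical(sum(out == 1L), 101L)
})

test_that("an empty mask filters to an empty labelling", {
  out <- labelAndFilterLesions(array(0L, c(5, 5, 5)), 100L)
  expect_identical(max(out), 0L)
  expect_length(attr(out, "keptLabels"), 0L)
})

test_that("binary masks are labelled by 26-connectivity, matching a brute-force oracle", {
  set.seed(5)
  for (rep in 1:3) {
    m <- array(as.integer(runif(512) > 0.75), c(8, 8, 8))
    out <- labelAndFilterLesions(m, 0L)
    # oracle: repeated neighbourhood expansion from each unvisited voxel
    d <- dim(m)
    visited <- array(FALSE, d)
    sizes <- integer(0)
    coords <- which(m == 1L, arr.ind = TRUE)
    for (r in seq_len(nrow(coords))) {
      p <- coords[r, ]
      if (visited[p[1], p[2], p[3]]) next
      comp <- matrix(p, 1); visited[p[1], p[2], p[3]] <- TRUE; size <- 1L
      while (nrow(comp)) {
        nxt <- NULL
        for (q in seq_len(nrow(comp))) {
          for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
            v <- comp[q, ] + c(dx, dy, dz)
            if (any(v < 1) || any(v > d)) next
            if (m[v[1], v[2], v[3]] == 1L && !visited[v[1], v[2], v[3]]) {
              visited[v[1], v[2], v[3]] <- TRUE
              size <- size + 1L
              nxt <- rbind(nxt, v)
            }
          }
        }
        comp <- if (is.null(nxt)) matrix(numeric(0), 0, 3) else nxt
      }
      sizes <- c(sizes, size)
    }
    got <- tabulate(out[out > 0L])
    expect_setequal(got, sizes)
    expect_identical(sum(got), sum(m))
    # no surviving component at or below the threshold after filtering
    f <- labelAndFilterLesions(m, 3L)
    if (max(f) > 0L) expect_true(all(tabulate(f[f > 0L]) > 3L))
  }
})

test_that("tissue medians use majority membership and exclude lesions from WM", {
  mk <- function(vals) array(vals, c(6, 1, 1))
  pvw <- mk(c(1, 1, 1, 1, 0, 0))
  pvg <- mk(c(0, 0, 0, 0, 1, 0))
  pvc <- mk(c(0, 0, 0, 0, 0, 1))
  vol <- mk(c(1, 2, 3, 4, 0.5, 0.1))
  vols <- list(fspgr = vol, se = vol, flair = vol)
  maps <- list(wm = pvw, gm = pvg, csf = pvc)
  noLesion <- mk(rep(0, 6))
  tm <- tissueMedians(vols, maps, noLesion)
  expect_equal(tissueMedian(tm, "fspgr", "wm"), 2.5)  # even-count median
  lesion <- mk(c(0, 0, 0, 1, 0, 0))  # covers the WM voxel with value 4
  tm2 <- tissueMedians(vols, maps, lesion)
  expect_equal(tissueMedian(tm2, "fspgr", "wm"), 2)
  expect_length(wmIntensities(tm2, "fspgr"), 3L)
  # an empty tissue class errors with the class named
  expect_error(tissueMedians(vols, list(wm = pvw, gm = pvg, csf = mk(rep(0, 6))),
                             noLesion), "csf")
})

test_that("phantom tissue medians agree with a sort-based oracle and exclude lesion voxels", {
  subj <- smallSubject(seed = 13L)
  tm <- tissueMedians(volumes(subj), tissueMaps(subj),
                      lesionLabels(subj) > 0L)
  wmMember <- tissueMaps(subj)$wm > 0.5 & lesionLabels(subj) == 0L
  v <- volumes(subj)$fspgr[wmMember]
  sv <- sort(v)
  n <- length(sv)
  oracle <- if (n %% 2 == 1) sv[(n + 1) / 2] else mean(sv[n / 2 + 0:1])
  expect_equal(tissueMedian(tm, "fspgr", "wm"), oracle)
  # the retained WM multiset contains no lesion voxel intensity positions
  expect_length(wmIntensities(tm, "fspgr"), sum(wmMember))
})
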