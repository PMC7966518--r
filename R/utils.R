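#' @include AllClasses.R
NULL

.clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# Deterministic per-subject seed derived from the master seed by a fixed
# counter scheme; kept below 2^31 - 1.
.deriveSeed <- function(masterSeed, counter) {
  as.integer((as.numeric(masterSeed) + 99991 * as.numeric(counter)) %% 2147483629)
}

# Integer offsets of an axis-aligned ellipsoid with the given voxel radii,
# centred on (0, 0, 0).
.ellipsoidOffsets <- function(radii) {
  stopifnot(length(radii) == 3L, all(radii > 0))
  rx <- floor(radii[1]); ry <- floor(radii[2]); rz <- floor(radii[3])
  g <- expand.grid(dx = -rx:rx, dy = -ry:ry, dz = -rz:rz)
  keep <- (g$dx / radii[1])^2 + (g$dy / radii[2])^2 + (g$dz / radii[3])^2 <= 1
  as.matrix(g[keep, , drop = FALSE])
}

# Ellipsoid voxel radii whose discretized volume approximates `count` voxels,
# with anisotropy factors `aspect` (product 1).
.radiiForCount <- function(count, aspect = c(1, 1, 1)) {
  r0 <- (3 * count / (4 * pi))^(1 / 3)
  pmax(r0 * aspect, 0.8)
}

#' Trilinear interpolation of a 3D array at continuous voxel coordinates
#'
#' Coordinates are in 1-based voxel index space, where the integer coordinate
#' i is the centre of voxel i. Samples outside the grid are clamped to the
#' nearest edge value.
#'
#' @param arr 3D numeric array.
#' @param coords N x 3 matrix of continuous voxel coordinates.
#' @return Numeric vector of N interpolated values.
#' @keywords internal
trilinearSample <- function(arr, coords) {
  d <- dim(arr)
  stopifnot(length(d) == 3L, ncol(coords) == 3L)
  x <- pmin(pmax(coords[, 1], 1), d[1])
  y <- pmin(pmax(coords[, 2], 1), d[2])
  z <- pmin(pmax(coords[, 3], 1), d[3])
  x0 <- pmin(floor(x), d[1] - 1L); y0 <- pmin(floor(y), d[2] - 1L)
  z0 <- pmin(floor(z), d[3] - 1L)
  if (d[1] == 1L) x0 <- rep(1, length(x))
  if (d[2] == 1L) y0 <- rep(1, length(y))
  if (d[3] == 1L) z0 <- rep(1, length(z))
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  x1 <- pmin(x0 + 1L, d[1]); y1 <- pmin(y0 + 1L, d[2]); z1 <- pmin(z0 + 1L, d[3])
  idx <- function(i, j, k) arr[cbind(i, j, k)]
  v000 <- idx(x0, y0, z0); v100 <- idx(x1, y0, z0)
  v010 <- idx(x0, y1, z0); v110 <- idx(x1, y1, z0)
  v001 <- idx(x0, y0, z1); v101 <- idx(x1, y0, z1)
  v011 <- idx(x0, y1, z1); v111 <- idx(x1, y1, z1)
  v00 <- v000 * (1 - fx) + v100 * fx
  v10 <- v010 * (1 - fx) + v110 * fx
  v01 <- v001 * (1 - fx) + v101 * fx
  v11 <- v011 * (1 - fx) + v111 * fx
  v0 <- v00 * (1 - fy) + v10 * fy
  v1 <- v01 * (1 - fy) + v11 * fy
  v0 * (1 - fz) + v1 * fz
}

#' Label connected components of a 3D binary mask (26-connectivity)
#'
#' @param mask 3D logical or 0/1 numeric array.
#' @return 3D integer array; 0 = background, components numbered 1..K in
#'   order of their first (column-major) voxel.
#' @keywords internal
labelComponents3D <- function(mask) {
  d <- dim(mask)
  stopifnot(length(d) == 3L)
  fg <- as.vector(mask) != 0
  lab <- integer(length(fg))
  if (!any(fg)) return(array(lab, d))
  # 26-neighbour offsets expressed as coordinate deltas
  nb <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, , drop = FALSE]
  coord <- arrayInd(seq_along(fg), d)
  nextLab <- 0L
  unvisited <- fg
  repeat {
    seed <- which.max(unvisited)
    if (!unvisited[seed]) break
    nextLab <- nextLab + 1L
    frontier <- seed
    unvisited[seed] <- FALSE
    lab[seed] <- nextLab
    while (length(frontier)) {
      fc <- coord[frontier, , drop = FALSE]
      # all 26 neighbours of the frontier, kept in-bounds
      cand <- do.call(rbind, lapply(seq_len(nrow(nb)), function(i)
        sweep(fc, 2, nb[i, ], "+")))
      ok <- cand[, 1] >= 1 & cand[, 1] <= d[1] &
            cand[, 2] >= 1 & cand[, 2] <= d[2] &
            cand[, 3] >= 1 & cand[, 3] <= d[3]
      cand <- cand[ok, , drop = FALSE]
      lin <- unique(cand[, 1] + d[1] * (cand[, 2] - 1L) +
                      d[1] * d[2] * (cand[, 3] - 1L))
      lin <- lin[unvisited[lin]]
      if (length(lin)) {
        unvisited[lin] <- FALSE
        lab[lin] <- nextLab
        frontier <- lin
      } else frontier <- integer(0)
    }
  }
  array(lab, d)
}

# md5 checksums of a set of files, named by path relative to `root`
.fileChecksums <- function(paths, root = NULL) {
  sums <- tools::md5sum(paths)
  if (!is.null(root)) names(sums) <- sub(paste0("^", root, "/?"), "", names(sums))
  as.list(sums)
}
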