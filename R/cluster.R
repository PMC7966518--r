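#' @include AllClasses.R
NULL

.wcss <- function(X, lab) {
  s <- 0
  for (k in 1:2) {
    Xk <- X[lab == k, , drop = FALSE]
    if (nrow(Xk)) s <- s + sum(sweep(Xk, 2, colMeans(Xk))^2)
  }
  s
}

.assign2 <- function(X, c1, c2) {
  d1 <- rowSums(sweep(X, 2, c1)^2)
  d2 <- rowSums(sweep(X, 2, c2)^2)
  ifelse(d1 <= d2, 1L, 2L)
}

# Lloyd iterations from given centers; returns labels, centers, iterations
# used and convergence flag. The closing assignment is the "classify" pass:
# every point is reassigned to its nearest final center.
.lloyd2 <- function(X, c1, c2, maxIterations = 10L) {
  lab <- .assign2(X, c1, c2)
  converged <- FALSE
  it <- 0L
  while (it < maxIterations) {
    it <- it + 1L
    if (!any(lab == 1L) || !any(lab == 2L)) break
    n1 <- colMeans(X[lab == 1L, , drop = FALSE])
    n2 <- colMeans(X[lab == 2L, , drop = FALSE])
    shift <- sqrt(sum((n1 - c1)^2) + sum((n2 - c2)^2))
    c1 <- n1; c2 <- n2
    newLab <- .assign2(X, c1, c2)
    if (identical(newLab, lab) || shift < 1e-9) {
      lab <- newLab
      converged <- TRUE
      break
    }
    lab <- newLab
  }
  lab <- .assign2(X, c1, c2)
  list(labels = lab, centers = rbind(c1, c2), iterations = it,
       converged = converged)
}

# Deterministic candidate projection directions: principal components, their
# pairwise sums and differences, the coordinate axes, and the direction
# between the two most distant observations.
.candidateDirections <- function(X) {
  p <- ncol(X)
  Xc <- sweep(X, 2, colMeans(X))
  dirs <- list()
  sv <- tryCatch(svd(Xc, nu = 0), error = function(e) NULL)
  if (!is.null(sv)) {
    keep <- which(sv$d > max(sv$d) * 1e-12)
    for (j in keep) dirs <- c(dirs, list(sv$v[, j]))
    nv <- length(dirs)
    if (nv >= 2) for (a in 1:(nv - 1)) for (b in (a + 1):nv)
      dirs <- c(dirs, list(dirs[[a]] + dirs[[b]]), list(dirs[[a]] - dirs[[b]]))
  }
  for (j in seq_len(p)) {
    e <- numeric(p); e[j] <- 1
    dirs <- c(dirs, list(e))
  }
  D <- as.matrix(stats::dist(X))
  ij <- which(D == max(D), arr.ind = TRUE)[1, ]
  fp <- X[ij[2], ] - X[ij[1], ]
  if (sum(fp^2) > 0) dirs <- c(dirs, list(fp))
  dirs
}

#' Two-cluster K-means on lesion median intensities
#'
#' Lloyd-type K-means with K = 2 on the raw (unscaled) Euclidean distance
#' over the three per-lesion medians, capped at \code{maxIterations}
#' iterations and finished with a classification pass that reassigns every
#' lesion to its nearest final center. Initialization is a deterministic
#' multi-start: the observations are swept along a fixed set of data-derived
#' projection directions (principal components and their pairwise
#' sums/differences, the coordinate axes, and the farthest-pair direction);
#' each ordered split induces starting centers, every start is
#' Lloyd-refined, and the solution with the smallest within-cluster sum of
#' squares is kept. For small inputs every split is tried; for larger ones
#' the best splits under a prefix-sum WCSS sweep seed the refinements. The
#' procedure is fully deterministic: permuting the input rows changes
#' nothing but the label order.
#'
#' Clusters are canonicalized so cluster 1 has the lower center on the first
#' feature (FSPGR).
#'
#' @param features data.frame containing \code{median_fspgr},
#'   \code{median_se}, \code{median_flair} columns, or a numeric matrix of
#'   features (columns in that order).
#' @param maxIterations Lloyd iteration cap (default 10).
#' @return A [ClusterModel2-class] object.
#' @examples
#' set.seed(1)
#' X <- rbind(matrix(rnorm(30, 0), 10), matrix(rnorm(30, 6), 10))
#' colnames(X) <- c("median_fspgr", "median_se", "median_flair")
#' fitKMeans2(as.data.frame(X))
#' @export
fitKMeans2 <- function(features, maxIterations = 10L) {
  X <- .featureMatrix(features)
  n <- nrow(X)
  if (n < 2L || nrow(unique(X)) < 2L)
    stop("need at least 2 lesions with distinct feature vectors")
  Xc <- sweep(X, 2, colMeans(X))
  dirs <- .candidateDirections(X)
  best <- NULL
  bestW <- Inf
  for (v in dirs) {
    proj <- drop(Xc %*% v)
    ord <- order(proj)
    splits <- seq_len(n - 1L)
    if (n > 100L) {
      # prefix-sum WCSS along the sweep; keep the most promising splits
      Xo <- X[ord, , drop = FALSE]
      cs <- apply(Xo, 2, cumsum)
      cs2 <- cumsum(rowSums(Xo^2))
      k <- seq_len(n - 1L)
      tot <- cs[n, ]; tot2 <- cs2[n]
      ss1 <- cs2[k] - rowSums(cs[k, , drop = FALSE]^2) / k
      ss2 <- (tot2 - cs2[k]) -
        rowSums(sweep(cs[k, , drop = FALSE], 2, tot, function(a, b) (b - a))^2) / (n - k)
      splits <- k[order(ss1 + ss2)][seq_len(min(12L, n - 1L))]
    }
    for (k in splits) {
      g1 <- ord[seq_len(k)]
      c1 <- colMeans(X[g1, , drop = FALSE])
      c2 <- colMeans(X[-g1, , drop = FALSE])
      fit <- .lloyd2(X, c1, c2, maxIterations)
      if (any(fit$labels == 1L) && any(fit$labels == 2L)) {
        w <- .wcss(X, fit$labels)
        if (w < bestW - 1e-12) {
          bestW <- w
          best <- fit
        }
      }
    }
  }
  if (is.null(best)) stop("2-means failed to produce two non-empty clusters")
  lab <- best$labels
  cen <- best$centers
  # canonical order: cluster 1 has the lower center on the first feature
  if (cen[1, 1] > cen[2, 1]) {
    lab <- 3L - lab
    cen <- cen[2:1, , drop = FALSE]
  }
  dimnames(cen) <- list(c("cluster1", "cluster2"), colnames(X))
  # influence F needs >= 2 lesions per cluster; singleton clusters can be
  # optimal on tiny inputs, in which case F is undefined
  fF <- if (min(sum(lab == 1L), sum(lab == 2L)) >= 2L)
    featureInfluenceF(X, lab)
  else stats::setNames(rep(NA_real_, ncol(X)), colnames(X))
  new("ClusterModel2",
      centers = cen,
      labels = lab,
      sizes = c(sum(lab == 1L), sum(lab == 2L)),
      featureF = fF,
      iterations = best$iterations,
      converged = best$converged)
}

.featureMatrix <- function(features) {
  if (is.matrix(features)) {
    X <- features
    if (is.null(colnames(X)))
      colnames(X) <- paste0("median_", .SEQUENCES)[seq_len(ncol(X))]
  } else {
    cols <- paste0("median_", .SEQUENCES)
    stopifnot(all(cols %in% names(features)))
    X <- as.matrix(features[, cols])
  }
  storage.mode(X) <- "double"
  X
}

#' Per-feature influence on the clustering (one-way ANOVA F)
#'
#' For each feature, the F ratio of the between-cluster mean square to the
#' within-cluster mean square across the final labels, with degrees of
#' freedom (1, n - 2). Features identical across all lesions get F = 0.
#'
#' @param features feature matrix or data.frame (as in [fitKMeans2()]).
#' @param labels integer cluster labels in {1, 2}.
#' @return Named numeric vector of F values, one per feature.
#' @export
featureInfluenceF <- function(features, labels) {
  X <- .featureMatrix(features)
  stopifnot(length(labels) == nrow(X))
  n1 <- sum(labels == 1L); n2 <- sum(labels == 2L)
  if (n1 < 2L || n2 < 2L)
    stop("within-cluster variance undefined: each cluster needs >= 2 lesions")
  n <- n1 + n2
  vapply(seq_len(ncol(X)), function(j) {
    x <- X[, j]
    gm <- mean(x)
    m1 <- mean(x[labels == 1L]); m2 <- mean(x[labels == 2L])
    ssb <- n1 * (m1 - gm)^2 + n2 * (m2 - gm)^2
    ssw <- sum((x[labels == 1L] - m1)^2) + sum((x[labels == 2L] - m2)^2)
    if (ssb == 0) return(0)
    if (ssw == 0) return(Inf)
    (ssb / 1) / (ssw / (n - 2))
  }, numeric(1)) |> stats::setNames(colnames(X))
}

#' Cluster summary in the two-column report layout
#'
#' Per-cluster lesion counts, final centers per sequence, and the median
#' (range) of the member lesions' median intensities per sequence.
#'
#' @param model a [ClusterModel2-class] (already canonical: cluster 1 has
#'   the lower FSPGR center).
#' @param features the feature table the model was fitted on.
#' @return data.frame with one row per (cluster, sequence) and columns
#'   cluster, sequence, n, center, median, min, max.
#' @export
clusterSummary <- function(model, features) {
  X <- .featureMatrix(features)
  lab <- clusterLabels(model)
  stopifnot(length(lab) == nrow(X))
  rows <- list()
  for (k in 1:2) {
    for (s in seq_len(ncol(X))) {
      x <- X[lab == k, s]
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = k, sequence = sub("^median_", "", colnames(X)[s]),
        n = sum(lab == k), center = centers(model)[k, s],
        median = stats::median(x), min = min(x), max = max(x))
    }
  }
  do.call(rbind, rows)
}
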