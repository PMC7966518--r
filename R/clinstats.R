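#' @include AllClasses.R
NULL

#' One-sample Wilcoxon signed-rank test against unity
#'
#' Tests whether standardized (tissue-relative) intensity ratios differ from
#' 1, i.e. whether lesions can be distinguished from the reference tissue.
#' Differences of exactly zero are dropped; the signed-rank statistic is
#' converted to a Z value by the tie-corrected normal approximation with
#' continuity correction, signed so that ratios below unity give Z < 0.
#'
#' @param ratios vector of standardized intensity ratios.
#' @return A list (class \code{bh_test}) with elements test, statistic (Z),
#'   p_value and n (non-unity sample size).
#' @export
wilcoxonVsUnity <- function(ratios) {
  d <- ratios - 1
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("all ratios are exactly 1: no nonzero differences")
  if (n < 5L) stop("need at least 5 non-unity ratios")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (W - mu - 0.5 * sign(W - mu)) / sqrt(sigma2)
  structure(list(test = "wilcoxon_signed_rank_vs_1", statistic = z,
                 W = W, p_value = 2 * stats::pnorm(-abs(z)), n = n),
            class = "bh_test")
}

#' Mann-Whitney U test between two groups of ratios
#'
#' Rank-sum comparison of two sets of standardized intensities (e.g. the
#' WM-relative ratios on SE versus FSPGR). The reported U is the number of
#' (a, b) pairs with a > b, counting ties as one half (equivalently, the
#' rank-sum U of the first group; the min/max convention is recorded in the
#' result). The tie-corrected normal approximation with continuity
#' correction gives Z and a two-sided p.
#'
#' @param groupA,groupB numeric vectors (non-empty).
#' @return A list (class \code{bh_test}) with elements test, U, statistic
#'   (Z), p_value, n (c(nA, nB)) and convention.
#' @export
mannWhitneyU <- function(groupA, groupB) {
  if (!length(groupA) || !length(groupB)) stop("both groups must be non-empty")
  nA <- length(groupA); nB <- length(groupB)
  r <- rank(c(groupA, groupB))
  U <- sum(r[seq_len(nA)]) - nA * (nA + 1) / 2
  mu <- nA * nB / 2
  N <- nA + nB
  ties <- table(r)
  sigma2 <- nA * nB / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  z <- if (sigma2 > 0) (U - mu - 0.5 * sign(U - mu)) / sqrt(sigma2) else 0
  p <- if (sigma2 > 0) 2 * stats::pnorm(-abs(z)) else 1
  structure(list(test = "mann_whitney_u", U = U, statistic = z,
                 p_value = min(p, 1), n = c(nA, nB),
                 convention = "U = pairs with groupA > groupB (ties count 1/2)"),
            class = "bh_test")
}

#' @export
print.bh_test <- function(x, ...) {
  cat(sprintf("%s: statistic Z = %.4f, p = %.4g (n = %s)\n",
              x$test, x$statistic, x$p_value, paste(x$n, collapse = "/")))
  invisible(x)
}

# Spearman rho with average-rank ties and a two-sided t-approximation p.
.spearman <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) return(list(rho = NA_real_, p = NA_real_, n = n))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n))
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) return(list(rho = rho, p = 0, n = n))
  tval <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(tval), n - 2), n = n)
}

#' Spearman correlations of lesion burden with clinical covariates,
#' Bonferroni-corrected
#'
#' Computes the full grid of Spearman rank correlations between every
#' burden measure and every clinical covariate, then applies Bonferroni
#' correction over the declared family (all cells with a defined
#' correlation): p_adjusted = min(1, m * p_raw). Pairs where either
#' variable is constant are flagged (NA) and excluded from the family size.
#'
#' @param burden data.frame keyed by \code{subject_id} with burden columns
#'   (e.g. from [burdenSummary()]).
#' @param clinical data.frame keyed by \code{subject_id} with clinical
#'   covariates.
#' @param burdenVars,clinicalVars column subsets to correlate; defaults to
#'   all non-key columns.
#' @return data.frame with columns burden, clinical, rho, p_raw,
#'   p_adjusted, n, and an attribute \code{familySize} (m).
#' @export
spearmanWithCorrection <- function(burden, clinical,
                                   burdenVars = setdiff(names(burden), "subject_id"),
                                   clinicalVars = setdiff(names(clinical), "subject_id")) {
  stopifnot("subject_id" %in% names(burden),
            "subject_id" %in% names(clinical))
  mg <- merge(burden, clinical, by = "subject_id")
  if (nrow(mg) < 3L) stop("need at least 3 subjects")
  rows <- list()
  for (b in burdenVars) {
    for (cv in clinicalVars) {
      s <- .spearman(mg[[b]], mg[[cv]])
      rows[[length(rows) + 1L]] <- data.frame(
        burden = b, clinical = cv, rho = s$rho, p_raw = s$p, n = s$n)
    }
  }
  out <- do.call(rbind, rows)
  m <- sum(!is.na(out$rho))
  out$p_adjusted <- pmin(1, m * out$p_raw)
  attr(out, "familySize") <- m
  out
}

#' Per-subject, per-cluster lesion burden
#'
#' Counts and summed volumes of lesions per cluster and in total, per
#' subject. Subjects without surviving lesions get zero rows.
#'
#' @param featureTable lesion feature table with \code{cluster_label} and
#'   \code{volume_mm3} columns.
#' @param subjectIds complete vector of subject identifiers (so that
#'   lesion-free subjects appear with zeros).
#' @return data.frame with columns subject_id, cl1_count, cl1_volume_mm3,
#'   cl2_count, cl2_volume_mm3, total_count, total_volume_mm3.
#' @export
burdenSummary <- function(featureTable, subjectIds = unique(featureTable$subject_id)) {
  stopifnot(all(c("subject_id", "volume_mm3", "cluster_label") %in%
                  names(featureTable)))
  agg <- function(id, k) {
    sel <- featureTable$subject_id == id &
      (if (is.null(k)) TRUE else featureTable$cluster_label == k)
    c(count = sum(sel), volume = sum(featureTable$volume_mm3[sel]))
  }
  out <- do.call(rbind, lapply(subjectIds, function(id) {
    a1 <- agg(id, 1L); a2 <- agg(id, 2L); at <- agg(id, NULL)
    data.frame(subject_id = id,
               cl1_count = a1["count"], cl1_volume_mm3 = a1["volume"],
               cl2_count = a2["count"], cl2_volume_mm3 = a2["volume"],
               total_count = at["count"], total_volume_mm3 = at["volume"])
  }))
  rownames(out) <- NULL
  out
}
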