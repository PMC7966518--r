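#' @include AllClasses.R utils.R
NULL

# Truncated-normal quantile function (inverse CDF restricted to [lower, upper])
.qtruncnorm <- function(p, mean, sd, lower = -Inf, upper = Inf) {
  a <- stats::pnorm((lower - mean) / sd)
  b <- stats::pnorm((upper - mean) / sd)
  mean + sd * stats::qnorm(a + p * (b - a))
}

#' Generate the clinical covariate table for a cohort
#'
#' Clinical covariates are coupled to class-2 lesion burden through a
#' Gaussian copula: each subject's analyzable class-2 lesion count (and
#' volume, for normalized brain volume) is converted to a normal score, a
#' correlated latent Gaussian is drawn with latent correlation
#' r = 2 sin(pi * rho / 6) (the Pearson correlation that yields a population
#' Spearman correlation of rho for a bivariate Gaussian copula), and the
#' latent value is mapped through the covariate's marginal quantile
#' function. Marginals: disease duration is truncated normal with mean 12.34
#' and sd 7.44 years (truncated at 0); EDSS is a truncated normal latent
#' mapped to the 0-10 scale in 0.5 steps (median ~2); normalized brain
#' volume is Gaussian around 1.5e6 with sd 8e4 (SIENAX-like arbitrary volume
#' units); relapse counts are independent Poisson draws.
#'
#' Only lesions above the analysis size filter contribute to the burden used
#' for coupling, so the injected associations refer to the burden the
#' analysis pipeline can actually measure.
#'
#' @param truthBySubject named list of per-subject truth data.frames (as
#'   stored in [SubjectPhantom-class] objects), one entry per subject.
#' @param spec the [CohortSpec-class] used to generate the cohort.
#' @param seed integer seed; defaults to the counter-0 seed derived from the
#'   master seed.
#' @param minLesionVoxels burden counts only lesions strictly larger than
#'   this (default 100, matching the analysis filter).
#' @return data.frame with columns subject_id, edss, disease_duration,
#'   n_relapses, n_relapses_since_treatment, nbv.
#' @export
generateClinicalTable <- function(truthBySubject, spec,
                                  seed = .deriveSeed(spec@masterSeed, 0L),
                                  minLesionVoxels = 100L) {
  validObject(spec)
  n <- length(truthBySubject)
  if (n != spec@nSubjects)
    stop("truthBySubject: expected one truth entry per subject (",
         spec@nSubjects, "), got ", n)
  ids <- names(truthBySubject)
  if (is.null(ids)) ids <- sprintf("S%03d", seq_len(n))
  voxVol <- prod(spec@voxelSize)
  cl2count <- vapply(truthBySubject, function(tr)
    sum(tr$class == 2L & tr$voxel_count > minLesionVoxels), numeric(1))
  cl2vol <- vapply(truthBySubject, function(tr)
    sum(tr$voxel_count[tr$class == 2L & tr$voxel_count > minLesionVoxels]) *
      voxVol, numeric(1))
  set.seed(as.integer(seed))
  zCount <- stats::qnorm((rank(cl2count, ties.method = "average") - 0.5) / n)
  zVol <- stats::qnorm((rank(cl2vol, ties.method = "average") - 0.5) / n)
  latent <- function(zb, rho) {
    r <- 2 * sin(pi * rho / 6)
    r * zb + sqrt(1 - r^2) * stats::rnorm(n)
  }
  es <- spec@effectSizes
  zEdss <- latent(zCount, es[["edss"]])
  zDur <- latent(zCount, es[["duration"]])
  zNbv <- latent(zVol, es[["nbv"]])
  edss <- .qtruncnorm(stats::pnorm(zEdss), mean = 2, sd = 1.6,
                      lower = 0, upper = 8)
  edss <- pmin(pmax(round(edss * 2) / 2, 0), 10)
  duration <- .qtruncnorm(stats::pnorm(zDur), mean = 12.34, sd = 7.44,
                          lower = 0)
  nbv <- 1.5e6 + 8e4 * zNbv
  relapses <- stats::rpois(n, 3)
  relapsesSince <- stats::rpois(n, 0.7)
  data.frame(subject_id = ids,
             edss = edss,
             disease_duration = duration,
             n_relapses = relapses,
             n_relapses_since_treatment = relapsesSince,
             nbv = nbv,
             row.names = NULL)
}
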