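# Small cohort specs used across tests: a scaled-down grid keeps single
# tests fast while preserving all structural features of the phantom
# (three compartments, two lesion classes, size filter straddling 100).

smallSpec <- function(nSubjects = 3L, masterSeed = 101L, ...) {
  args <- list(nSubjects = nSubjects,
               gridShape = c(48L, 48L, 40L),
               meanLesionsPerSubject = 4,
               lesionSizeRange = c(60, 400),
               masterSeed = masterSeed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(cohortSpec, args)
}

# a subject guaranteed to have at least one lesion (regenerates with
# consecutive seeds until one appears)
smallSubject <- function(seed = 7L, spec = smallSpec()) {
  for (s in seed + 0:20) {
    subj <- generateSubject(spec, s)
    if (nrow(lesionTruth(subj)) > 0) return(subj)
  }
  stop("no lesions in 20 attempts")
}

# brute-force WCSS of a 2-partition
bruteWcss <- function(X, lab) {
  s <- 0
  for (k in unique(lab)) {
    Xk <- X[lab == k, , drop = FALSE]
    s <- s + sum(sweep(Xk, 2, colMeans(Xk))^2)
  }
  s
}

# exhaustive minimum WCSS over all 2-partitions of up to ~16 points
bruteBest2 <- function(X) {
  n <- nrow(X)
  best <- Inf
  for (m in seq_len(2^(n - 1) - 1)) {
    lab <- as.integer(intToBits(m))[seq_len(n)] + 1L
    w <- bruteWcss(X, lab)
    if (w < best) best <- w
  }
  best
}
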