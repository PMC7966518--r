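test_that("ratios symmetric around unity give Z near 0 and p near 1", {
  res <- wilcoxonVsUnity(c(0.9, 1.1, 0.8, 1.2, 0.7, 1.3))
  expect_lt(abs(res$statistic), 0.5)
  expect_gt(res$p_value, 0.8)
})

test_that("ratios below unity give negative Z", {
  res <- wilcoxonVsUnity(seq(0.5, 0.95, by = 0.05))
  expect_lt(res$statistic, 0)
  expect_lt(res$p_value, 0.05)
})

test_that("degenerate Wilcoxon inputs are rejected", {
  expect_error(wilcoxonVsUnity(rep(1, 10)), "exactly 1")
  expect_error(wilcoxonVsUnity(c(0.9, 1.1, 1, 1)), "at least 5")
})

test_that("signed-rank statistic and p agree with the reference implementation", {
  set.seed(30)
  for (rep in 1:25) {
    x <- round(rlnorm(sample(8:40, 1), 0, 0.2), 2)  # rounding induces ties
    x <- x[x != 1]
    if (length(x) < 5) next
    res <- wilcoxonVsUnity(x)
    ref <- suppressWarnings(wilcox.test(x, mu = 1, exact = FALSE,
                                        correct = TRUE))
    expect_equal(res$W, unname(ref$statistic))
    expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("Mann-Whitney U handles complete separation and identical groups", {
  res <- mannWhitneyU(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  ident <- mannWhitneyU(1:10, 1:10)
  expect_gt(ident$p_value, 0.9)
})

test_that("U equals the brute-force pairwise comparison count, p matches the reference", {
  set.seed(31)
  for (rep in 1:25) {
    a <- round(rnorm(sample(5:30, 1)), 1)
    b <- round(rnorm(sample(5:30, 1), 0.3), 1)
    res <- mannWhitneyU(a, b)
    brute <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
    expect_equal(res$U, brute)
    ref <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
    expect_equal(res$U, unname(ref$statistic))
    expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("Spearman rho matches the closed-form rank formula and is monotone-invariant", {
  x <- c(3, 1, 4, 9, 7)
  y <- c(2, 0, 8, 6, 5)
  s <- bhtyper:::.spearman(x, y)
  d <- rank(x) - rank(y)
  expect_equal(s$rho, 1 - 6 * sum(d^2) / (5 * 24))
  # invariance under strictly monotone transforms of either variable
  s2 <- bhtyper:::.spearman(exp(x), y^3)
  expect_equal(s2$rho, s$rho)
  # perfect association
  expect_equal(bhtyper:::.spearman(1:10, (1:10)^2)$rho, 1)
})

test_that("Spearman p agrees with the reference t-approximation", {
  set.seed(32)
  for (rep in 1:25) {
    n <- sample(8:40, 1)
    x <- rnorm(n); y <- 0.4 * x + rnorm(n)
    s <- bhtyper:::.spearman(x, y)
    ref <- suppressWarnings(cor.test(x, y, method = "spearman",
                                     exact = FALSE))
    expect_equal(s$rho, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(s$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("Bonferroni adjustment is min(1, m * p) over the defined family", {
  set.seed(33)
  n <- 20
  burden <- data.frame(subject_id = sprintf("S%02d", 1:n),
                       b1 = rnorm(n), b2 = rnorm(n),
                       bconst = rep(1, n))
  clinical <- data.frame(subject_id = sprintf("S%02d", 1:n),
                         c1 = rnorm(n), c2 = rnorm(n))
  out <- spearmanWithCorrection(burden, clinical)
  m <- attr(out, "familySize")
  expect_identical(m, 4L)  # constant burden column is excluded
  ok <- !is.na(out$rho)
  expect_equal(out$p_adjusted[ok], pmin(1, m * out$p_raw[ok]))
  expect_true(all(is.na(out$p_adjusted[!ok])))
  expect_true(all(out$p_adjusted[ok] >= out$p_raw[ok]))
  # mid-size raw p values cap at exactly 1
  expect_true(any(out$p_adjusted[ok] == 1))
})

test_that("burden summary aggregates counts and volumes per cluster with zero rows", {
  ft <- data.frame(subject_id = c("A", "A", "A"),
                   lesion_id = 1:3,
                   volume_mm3 = c(10, 20, 30),
                   cluster_label = c(1L, 1L, 2L))
  out <- burdenSummary(ft, subjectIds = c("A", "B"))
  a <- out[out$subject_id == "A", ]
  expect_equal(a$cl1_count, 2)
  expect_equal(a$cl1_volume_mm3, 30)
  expect_equal(a$cl2_count, 1)
  expect_equal(a$cl2_volume_mm3, 30)
  expect_equal(a$total_count, 3)
  expect_equal(a$total_volume_mm3, 60)
  b <- out[out$subject_id == "B", ]
  expect_true(all(b[, -1] == 0))
})

test_that("burden totals equal an independent group-by aggregation", {
  set.seed(34)
  ft <- data.frame(subject_id = sample(sprintf("S%d", 1:6), 60, replace = TRUE),
                   lesion_id = 1:60,
                   volume_mm3 = runif(60, 100, 2000),
                   cluster_label = sample(1:2, 60, replace = TRUE))
  out <- burdenSummary(ft, subjectIds = sprintf("S%d", 1:6))
  oracle <- aggregate(volume_mm3 ~ subject_id, ft, sum)
  for (i in seq_len(nrow(oracle))) {
    expect_equal(out$total_volume_mm3[out$subject_id == oracle$subject_id[i]],
                 oracle$volume_mm3[i])
  }
  expect_equal(sum(out$cl1_count + out$cl2_count), 60)
})
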