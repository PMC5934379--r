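.mkExpr <- function(nr, nc, prefix = "P", seed = 1) {
  withr::local_seed(seed, .local_envir = parent.frame())
  m <- matrix(rnorm(nr * nc, 8, 1), nrow = nr,
              dimnames = list(paste0(prefix, seq_len(nr)),
                              paste0("s", seq_len(nc))))
  m
}

test_that("mergePlatforms intersects probes and concatenates samples", {
  m1 <- matrix(1:4, 2, dimnames = list(c("P1", "P2"), c("a", "b")))
  m2 <- matrix(5:8, 2, dimnames = list(c("P2", "P3"), c("c", "d")))
  got <- suppressMessages(mergePlatforms(m1, m2))
  x <- SummarizedExperiment::assay(got)
  expect_identical(rownames(x), "P2")
  expect_identical(colnames(x), c("a", "b", "c", "d"))

  m3 <- matrix(1:4, 2, dimnames = list(c("P1", "P2"), c("e", "f")))
  same <- suppressMessages(mergePlatforms(m1, m3))
  expect_equal(dim(SummarizedExperiment::assay(same)), c(2L, 4L))

  big1 <- .mkExpr(100, 3, seed = 2)
  big2 <- .mkExpr(80, 2, seed = 3)
  rownames(big2) <- paste0("P", 41:120)
  colnames(big2) <- c("x1", "x2")
  expect_message(merged <- mergePlatforms(big1, big2), "40 \\+ 20")
  expect_equal(nrow(SummarizedExperiment::assay(merged)), 60)

  m4 <- matrix(1:2, 1, 2, dimnames = list("Q9", c("g", "h")))
  expect_error(mergePlatforms(m1, m4), "no shared")
})

test_that("quantile normalization equalizes sample distributions", {
  m <- cbind(s1 = c(1, 2, 3), s2 = c(4, 5, 6))
  rownames(m) <- paste0("P", 1:3)
  qn <- quantileNormalize(m)
  expect_equal(unname(qn[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(qn[, 2]), c(2.5, 3.5, 4.5))

  # identical columns are a fixed point
  ident <- cbind(s1 = c(3, 1, 2), s2 = c(3, 1, 2))
  rownames(ident) <- paste0("P", 1:3)
  expect_equal(quantileNormalize(ident), ident)

  # all columns share the same sorted values, rank order preserved
  m2 <- .mkExpr(100, 6, seed = 4)
  qn2 <- quantileNormalize(m2)
  ref <- unname(sort(qn2[, 1]))
  for (j in 2:6)
    expect_equal(unname(sort(qn2[, j])), ref, tolerance = 1e-12)
  expect_identical(apply(qn2, 2, rank), apply(m2, 2, rank))

  m2[1, 1] <- NA
  expect_error(quantileNormalize(m2), "missing")
})

test_that("quantile normalization is idempotent", {
  m <- .mkExpr(200, 8, seed = 5)
  qn <- quantileNormalize(m)
  expect_equal(quantileNormalize(qn), qn, tolerance = 1e-10)
})

test_that("summarizeToGene takes the per-gene median and drops unmapped", {
  m <- rbind(P1 = c(1, 10), P2 = c(3, 11), P3 = c(100, 12), P4 = c(7, 13))
  colnames(m) <- c("s1", "s2")
  map <- c(P1 = "GA", P2 = "GA", P3 = "GA", P4 = "GB")
  got <- SummarizedExperiment::assay(summarizeToGene(m, map))
  expect_equal(unname(got["GA", "s1"]), 3)   # median of 1, 3, 100
  expect_equal(unname(got["GB", ]), c(7, 13))  # single probe copied

  map2 <- c(P1 = "GA", P2 = "GB", P3 = "GC")
  expect_message(g2 <- summarizeToGene(m, map2), "1 unmapped")
  expect_equal(nrow(SummarizedExperiment::assay(g2)), 3)

  expect_error(summarizeToGene(m, c(Q1 = "GX")), "no probe maps")
})

test_that("gene summarization commutes with sample permutation", {
  m <- .mkExpr(10, 5, seed = 6)
  map <- setNames(rep(paste0("G", 1:4), length.out = 10), rownames(m))
  a <- SummarizedExperiment::assay(summarizeToGene(m, map))
  expect_equal(nrow(a), 4)
  perm <- c(3, 1, 5, 2, 4)
  b <- SummarizedExperiment::assay(summarizeToGene(m[, perm], map))
  expect_equal(b, a[, perm])
})

test_that("flagOutlierSamples finds planted outliers, order-invariantly", {
  withr::local_seed(7)
  template <- rnorm(300, 8, 1)
  good <- vapply(1:20, function(i) template + rnorm(300, sd = 0.3),
                 numeric(300))
  bad <- vapply(1:2, function(i) sample(template), numeric(300))
  m <- cbind(good, bad)
  dimnames(m) <- list(paste0("P", 1:300), c(paste0("g", 1:20), "o1", "o2"))
  fl <- flagOutlierSamples(m, thresholdSD = 2)
  expect_setequal(fl$flagged, c("o1", "o2"))
  expect_s3_class(fl$dendrogram, "hclust")

  perm <- sample(ncol(m))
  fl2 <- flagOutlierSamples(m[, perm], thresholdSD = 2)
  expect_setequal(fl2$flagged, fl$flagged)

  # homogeneous cohort: nothing flagged
  fl3 <- flagOutlierSamples(good, thresholdSD = 2)
  expect_length(fl3$flagged, 0)

  # constant sample flagged as degenerate
  m2 <- cbind(good[, 1:5], flat = rep(1, 300))
  colnames(m2) <- c(paste0("g", 1:5), "flat")
  fl4 <- flagOutlierSamples(m2, thresholdSD = 2)
  expect_true("flat" %in% fl4$degenerate)
  expect_true("flat" %in% fl4$flagged)
})

test_that("a 78-sample cohort with 2 planted outliers retains 76", {
  cs <- simulateCohort(seed = 12)
  pr <- simulateProbeLevel(cs$markers, nOutliers = 2, seed = 12)
  genes <- suppressMessages(
    summarizeToGene(quantileNormalize(pr$probes), pr$probe2gene))
  expect_equal(ncol(SummarizedExperiment::assay(genes)), 78)
  fl <- flagOutlierSamples(genes)
  expect_setequal(fl$flagged, pr$outlierIds)
  retained <- setdiff(colnames(SummarizedExperiment::assay(genes)),
                      fl$flagged)
  expect_length(retained, 76)
})
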