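test_that("frequency estimation is alt/(ref+alt) with a depth floor", {
  ac <- alleleCounts(ref = cbind(P1 = c(3L, 0L), P2 = c(10L, 5L)),
                     alt = cbind(P1 = c(7L, 0L), P2 = c(2L, 5L)),
                     chromosome = c("chr1", "chr1"), position = 1:2)
  f <- estimateFrequencies(ac)
  expect_equal(unname(alleleFreqs(f)[1, "P1"]), 0.7)
  expect_true(is.na(alleleFreqs(f)[2, "P1"]))    # 0/0 is missing
  expect_false(any(SummarizedExperiment::rowData(f)$allMissing))
  f11 <- estimateFrequencies(ac, minDepth = 11L)
  expect_true(is.na(alleleFreqs(f11)[1, "P1"]))  # depth 10 < floor of 11
  expect_false(is.na(alleleFreqs(f11)[1, "P2"]))
})

test_that("pool frequency estimates are unbiased at depth", {
  truth <- fm(matrix(0.25, 1e4, 1, dimnames = list(NULL, "P1")))
  ac <- simulatePoolseq(truth, poolSize = 48, depth = 100, seed = 21)
  f <- alleleFreqs(estimateFrequencies(ac))
  expect_equal(mean(f, na.rm = TRUE), 0.25, tolerance = 0.04)
  expect_lt(abs(mean(f, na.rm = TRUE) - 0.25), 0.01)
})

test_that("block covariance handles duplicated and constant columns", {
  set.seed(22)
  x <- runif(600, 0.2, 0.8)
  f <- fm(cbind(P1 = x, P2 = x, P3 = runif(600, 0.2, 0.8)))
  cv <- blockCovariance(f, 100)
  m <- covMatrix(cv)
  expect_equal(m["P1", "P2"], m["P1", "P1"], tolerance = 1e-12)
  expect_equal(m["P1", "P2"], m["P2", "P2"], tolerance = 1e-12)
  const <- fm(matrix(0.5, 400, 3, dimnames = list(NULL, paste0("P", 1:3))))
  expect_equal(max(abs(covMatrix(blockCovariance(const, 100)))), 0)
  expect_error(blockCovariance(fm(matrix(runif(50 * 3), 50, 3,
    dimnames = list(NULL, paste0("P", 1:3)))), 100), "fewer than 2")
})

test_that("block point estimate equals the full-data covariance on
           homogeneous blocks, and blocks never span chromosomes", {
  set.seed(23)
  f0 <- matrix(runif(1200, 0, 1), 400, 3, dimnames = list(NULL, paste0("P", 1:3)))
  cv <- blockCovariance(fm(f0), 100)
  y <- f0 - rowMeans(f0)
  expect_equal(covMatrix(cv), crossprod(y) / nrow(y), tolerance = 1e-8)
  # 250 SNPs on each of two chromosomes with block size 100: the trailing
  # 50 SNPs of each chromosome are dropped, giving 4 blocks
  f2 <- fm(matrix(runif(1500), 500, 3, dimnames = list(NULL, paste0("P", 1:3))),
           chrom = rep(c("chr1", "chr2"), each = 250),
           pos = rep(seq_len(250), 2))
  expect_identical(blockCovariance(f2, 100)@nBlocks, 4L)
})

test_that("standard errors shrink with the number of blocks", {
  g <- starGraph(0.05, 0.05)
  f1 <- simulateFrequencies(g, 1e4, midRootDist(), seed = 24)
  f2 <- simulateFrequencies(g, 4e4, midRootDist(), seed = 25)
  r <- mean(covSE(blockCovariance(f1, 100))) /
       mean(covSE(blockCovariance(f2, 100)))
  expect_equal(r, 2, tolerance = 0.35)   # 1/sqrt(nBlocks) scaling
})

test_that("star-tree off-diagonal covariances sit within 2 SE of zero", {
  g <- starGraph(0.08, 0.05)
  f <- simulateFrequencies(g, 5e4, midRootDist(), seed = 26)
  cv <- blockCovariance(f, 100)
  V <- expectedCovariance(g, scale = "frequency", centered = TRUE,
                          rootFreqDist = midRootDist())
  p <- populations(f)
  # the centered model moves mass off the diagonal; compare to it, and
  # check the uncentered star has no shared drift at all
  expect_true(all(abs(covMatrix(cv)[p, p] - V[p, p]) <=
                  2 * covSE(cv)[p, p] + 1e-12))
  expect_equal(expectedCovariance(g)["A", "B"], 0)
})

test_that("PCA is an SVD of the centered, unscaled frequency matrix", {
  set.seed(27)
  f0 <- matrix(runif(5 * 200), 5, 200)
  rownames(f0) <- paste0("P", 1:5)
  fmx <- fm(t(f0))
  pc <- pcaScores(fmx)
  expect_equal(sum(pc$varianceFraction), 1)
  X <- scale(f0, center = TRUE, scale = FALSE)
  recon <- pc$scores %*% t(pc$loadings)
  expect_equal(unname(recon), unname(X), tolerance = 1e-8,
               ignore_attr = TRUE)
  # duplicated populations get identical scores
  fdup <- fm(t(rbind(f0, P6 = f0["P1", ])))
  pcd <- pcaScores(fdup)
  expect_equal(pcd$scores["P6", ], pcd$scores["P1", ], tolerance = 1e-10)
})

test_that("PC1 separates two deeply split clusters", {
  g <- populationGraph(data.frame(
    parent = c("R", "R", "I", "I", "I", "J", "J", "J", "R"),
    child  = c("I", "J", "A1", "A2", "A3", "B1", "B2", "B3", "O"),
    drift  = c(0.2, 0.2, 0.01, 0.01, 0.01, 0.01, 0.01, 0.01, 0)),
    outgroup = "O")
  f <- simulateFrequencies(g, 5000, midRootDist(), seed = 28)
  pc <- pcaScores(f, exclude = "O")
  s <- pc$scores[, "PC1"]
  gap <- function(v) min(v[4:6]) - max(v[1:3])
  a <- s[c("A1", "A2", "A3")]; b <- s[c("B1", "B2", "B3")]
  # sign-invariant: one cluster strictly above the other on PC1
  expect_true(max(a) < min(b) || max(b) < min(a))
})

test_that("allele coding applies the 0.95 common-allele rule", {
  fmx <- fm(cbind(P1 = c(0.97, 0.5, 0.03, NA, 0.95, 0.05)))
  calls <- codedCalls(codeAlleles(fmx))[, 1]
  expect_identical(unname(calls), c("ALT", "N", "REF", "N", "ALT", "REF"))
  # configurable threshold, comparison is >=
  calls9 <- codedCalls(codeAlleles(fmx, threshold = 0.9))[, 1]
  expect_identical(unname(calls9[2]), "N")
  expect_error(codeAlleles(fmx, threshold = 0.5))
})
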