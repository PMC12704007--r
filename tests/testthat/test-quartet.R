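codedFromStates <- function(states) {
  # states: matrix of "REF"/"ALT"/"N" with columns X, Y, Z, O
  ancestryMosaic:::.codedAlleles(
    states, ancestryMosaic:::.snpRanges(rep("chr1", nrow(states)),
                                        seq_len(nrow(states))))
}

test_that("votes follow the shared-derived rule with outgroup polarization", {
  states <- rbind(
    c("ALT", "ALT", "REF", "REF"),  # X,Y derived -> topology 1
    c("ALT", "REF", "ALT", "REF"),  # X,Z derived -> topology 2
    c("REF", "ALT", "ALT", "REF"),  # Y,Z derived -> topology 3
    c("REF", "REF", "ALT", "ALT"),  # polarity flips with the outgroup
    c("ALT", "ALT", "ALT", "REF"),  # all derived -> uninformative
    c("ALT", "REF", "REF", "REF"),  # singleton -> uninformative
    c("ALT", "ALT", "N",   "REF"),  # any N -> uninformative
    c("REF", "REF", "REF", "REF"))  # invariant -> uninformative
  colnames(states) <- c("X", "Y", "Z", "O")
  v <- snpVote(codedFromStates(states), c("X", "Y", "Z", "O"))
  expect_identical(v, c(1L, 2L, 3L, 1L, NA, NA, NA, NA))
})

test_that("swapping X and Y permutes topologies 2 and 3 exactly", {
  set.seed(41)
  states <- matrix(sample(c("REF", "ALT", "N"), 400, TRUE, c(.4, .4, .2)),
                   100, 4, dimnames = list(NULL, c("X", "Y", "Z", "O")))
  cd <- codedFromStates(states)
  v1 <- snpVote(cd, c("X", "Y", "Z", "O"))
  v2 <- snpVote(cd, c("Y", "X", "Z", "O"))
  expect_identical(v1 == 1L, v2 == 1L)
  expect_identical(v1 == 2L, v2 == 3L)
  expect_identical(v1 == 3L, v2 == 2L)
})

test_that("window scores normalize averaged counts and flag empty windows", {
  # one 10-kb base window with votes (3, 1, 0)
  v <- c(1L, 1L, 1L, 2L)
  gr <- windowScores(v, position = c(100L, 2000L, 5000L, 9000L),
                     baseWindow = 10000L, slideWindow = 10000L,
                     step = 10000L)
  expect_equal(S4Vectors::mcols(gr)$score1, 0.75)
  expect_equal(S4Vectors::mcols(gr)$score2, 0.25)
  expect_equal(S4Vectors::mcols(gr)$score3, 0)
  expect_identical(S4Vectors::mcols(gr)$nInformative, 4L)
  expect_identical(GenomicRanges::start(gr), 1L)
  expect_identical(GenomicRanges::end(gr), 10000L)
  # all-empty windows: missing scores, no division by zero
  gre <- windowScores(rep(NA_integer_, 3), position = c(1L, 5L, 9L) * 1000L,
                      chromosomeLength = 50000L)
  expect_true(all(is.na(S4Vectors::mcols(gre)$score1)))
  expect_identical(S4Vectors::mcols(gre)$nInformative, 0L)
  # configuration errors
  expect_error(windowScores(v, 1:4, slideWindow = 50000L, step = 30000L),
               "configuration error")
})

test_that("scores sum to one on every informative window", {
  set.seed(42)
  v <- sample(c(1:3, NA), 5000, TRUE)
  pos <- sort(sample.int(3e5, 5000))
  gr <- windowScores(v, pos, chromosomeLength = 3e5)
  df <- as.data.frame(S4Vectors::mcols(gr))
  inf <- df$nInformative > 0
  expect_true(all(abs(rowSums(df[inf, 1:3]) - 1) < 1e-12))
  expect_true(all(is.na(df$score1[!inf])))
})

test_that("score summaries use the population variance convention", {
  mk <- function(ch, s1) GenomicRanges::GRanges(ch,
    IRanges::IRanges(start = c(1, 10001), width = 50000),
    score1 = s1, score2 = 1 - s1, score3 = 0, nInformative = 10L)
  gr <- suppressWarnings(c(mk("chr1", c(0.2, 0.2)), mk("chr2", c(0.8, 0.8))))
  s <- scoreSummaries(gr)
  expect_equal(unname(s$withinChromosomeVariance), c(0, 0))
  expect_equal(s$meanWithinVariance, 0)
  # chromosome means 0.2 and 0.8: population variance is 0.09
  expect_equal(s$amongChromosomeVariance, 0.09)
  expect_equal(unname(s$chromosomeMeans[, "score1"]), c(0.2, 0.8))
})

test_that("size-score correlation is exact on a line and calibrated
           under permutation", {
  sizes <- setNames(seq(1e6, 2.2e6, length.out = 10), paste0("chr", 1:10))
  scores <- setNames(0.1 + 0.4 * seq(0, 1, length.out = 10), names(sizes))
  r <- scoreSizeCorrelation(scores, sizes)
  expect_equal(r$r, 1)
  # excluded chromosomes drop out
  scores2 <- c(scores, Z = 0.99)
  sizes2 <- c(sizes, Z = 3e6)
  expect_equal(scoreSizeCorrelation(scores2, sizes2, exclude = "Z")$r, 1)
  # permuting scores detaches them from size: P roughly uniform
  set.seed(43)
  ps <- replicate(400, scoreSizeCorrelation(
    setNames(sample(scores), names(scores)), sizes)$p.value)
  expect_gt(mean(ps), 0.4)
  expect_lt(mean(ps), 0.6)
  expect_gt(mean(ps < 0.25), 0.15)
})

test_that("a topology-1 history dominates window scores; admixture toward
           a size-linked fraction flips the correlation sign", {
  g1 <- populationGraph(data.frame(
    parent = c("R", "R", "I", "I", "I2", "I2"),
    child  = c("O", "I", "Z", "I2", "X", "Y"),
    drift  = 0.4), outgroup = "O")
  m <- vapply(1:5, function(s) {
    f <- simulateFrequencies(g1, 5000, sfsRootDist(), seed = 50 + s,
                             position = seq.int(100, by = 200,
                                                length.out = 5000))
    gr <- quartetScan(codeAlleles(f), c("X", "Y", "Z", "O"),
                      chromosomeSizes = c(chr1 = 1e6))
    mean(S4Vectors::mcols(gr)$score1, na.rm = TRUE)
  }, numeric(1))
  expect_gt(mean(m, na.rm = TRUE), 0.9)
})
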