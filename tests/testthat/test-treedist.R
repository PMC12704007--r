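test_that("chromosome trees recover a known strongly drifted topology and
           are invariant to SNP order", {
  g8 <- populationGraph(data.frame(
    parent = c("R", "R", "I", "I", "J", "J", "K", "K", "R"),
    child  = c("I", "J", "A", "B", "C", "K", "D", "E", "O"),
    drift  = 0.3), outgroup = "O")
  f <- simulateFrequencies(g8, 2e4, rootDist("beta", shape1 = 2, shape2 = 2),
                           seed = 61)
  cd <- codeAlleles(f)
  tr <- chromosomeTree(cd, "O")
  expect_equal(clusteringInfoDistance(tr, graphToPhylo(g8)), 0)
  # permuting SNP rows leaves the tree unchanged
  set.seed(62)
  perm <- sample(nrow(cd))
  trP <- ancestryMosaic:::.treeFromCalls(codedCalls(cd)[perm, ], "O", 100L)
  expect_equal(clusteringInfoDistance(trP, tr), 0)
})

test_that("a duplicated population is placed as sibling of its source", {
  g <- balancedTree(d = 0.3)
  f <- simulateFrequencies(g, 5000, rootDist("beta", shape1 = 2, shape2 = 2),
                           seed = 63)
  cl <- codedCalls(codeAlleles(f))
  cl <- cbind(cl, A2 = cl[, "A"])
  tr <- ancestryMosaic:::.treeFromCalls(cl, "O", 100L)
  sibs <- ape::extract.clade(tr, ape::getMRCA(tr, c("A", "A2")))$tip.label
  expect_setequal(sibs, c("A", "A2"))
})

test_that("estimation refuses too few usable SNPs", {
  cl <- matrix("N", 50, 4, dimnames = list(NULL, c("A", "B", "C", "O")))
  cl[1:20, ] <- "ALT"
  expect_error(ancestryMosaic:::.treeFromCalls(cl, "O", 100L),
               "estimation error")
})

test_that("clustering-information distance is a proper topology distance
           and matches the brute-force matching oracle", {
  set.seed(64)
  for (rep in 1:12) {
    t1 <- ape::rtree(6, tip.label = paste0("t", 1:6))
    t2 <- ape::rtree(6, tip.label = paste0("t", 1:6))
    d12 <- clusteringInfoDistance(t1, t2)
    expect_equal(d12, bruteForceCID(t1, t2), tolerance = 1e-12)
    expect_equal(d12, clusteringInfoDistance(t2, t1))        # symmetry
    expect_equal(clusteringInfoDistance(t1, t1), 0)
    expect_gte(d12, 0)
    # zero iff identical split sets, in step with plain RF
    expect_identical(plainRF(t1, t2) == 0L, abs(d12) < 1e-12)
  }
  expect_error(clusteringInfoDistance(
    ape::rtree(5), ape::rtree(5, tip.label = letters[1:5])), "leaf set")
})

test_that("plain RF counts conflicting splits and agrees with phangorn", {
  t1 <- ape::read.tree(text = "((A,B),(C,D));")
  t2 <- ape::read.tree(text = "((A,C),(B,D));")
  expect_equal(plainRF(t1, t1), 0)
  expect_equal(plainRF(t1, t2), 2)   # one conflicting split in each tree
  set.seed(65)
  for (rep in 1:8) {
    a <- ape::rtree(7, tip.label = paste0("t", 1:7))
    b <- ape::rtree(7, tip.label = paste0("t", 1:7))
    expect_equal(plainRF(a, b),
                 as.integer(phangorn::RF.dist(ape::unroot(a), ape::unroot(b))))
  }
})

test_that("the permutation test preserves counts, bounds P away from zero,
           and detects truly different chromosome histories", {
  T1 <- balancedTree(c("A", "B", "C", "D", "E"), d = 0.3)
  T2 <- balancedTree(c("A", "D", "C", "B", "E"), d = 0.3)
  rd <- rootDist("beta", shape1 = 2, shape2 = 2)
  nsnp <- 2000L
  fT1 <- simulateFrequencies(T1, 3 * nsnp, rd, seed = 66,
           chromosome = rep(paste0("chr", 1:3), each = nsnp),
           position = rep(seq_len(nsnp), 3))
  fT2 <- simulateFrequencies(T2, nsnp, rd, seed = 67,
           chromosome = rep("chr4", nsnp), position = seq_len(nsnp))
  cl <- rbind(codedCalls(codeAlleles(fT1)), codedCalls(codeAlleles(fT2)))
  cd <- ancestryMosaic:::.codedAlleles(cl, ancestryMosaic:::.snpRanges(
    c(snpChromosomes(fT1), snpChromosomes(fT2)),
    c(snpPositions(fT1), snpPositions(fT2))))
  res <- permutationTest(cd, "O", nPermutations = 50, seed = 68)
  expect_identical(res@nPermutations, 50L)
  expect_gte(pValue(res), 1 / 51)
  expect_equal(pValue(res), 1 / 51)   # observed beats every permutation
  d <- distanceMatrix(res)
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  expect_length(nullMeans(res), 50)
  # distances only involve chr4 vs the rest
  expect_gt(min(d["chr4", c("chr1", "chr2", "chr3")]), 0)
  expect_equal(max(d[1:3, 1:3]), 0)
})

test_that("detection strengthens with the drift separating the two
           chromosome classes", {
  rd <- rootDist("beta", shape1 = 2, shape2 = 2)
  hit <- vapply(c(0.05, 0.15, 0.3), function(d) {
    T1 <- balancedTree(c("A", "B", "C", "D", "E"), d = d)
    T2 <- balancedTree(c("A", "D", "C", "B", "E"), d = d)
    mean(vapply(1:8, function(r) {
      f1 <- simulateFrequencies(T1, 3000, rd, seed = 700 + 13 * r + d * 1000,
              chromosome = rep(paste0("chr", 1:3), each = 1000),
              position = rep(seq_len(1000), 3))
      f2 <- simulateFrequencies(T2, 1000, rd, seed = 900 + 13 * r + d * 1000,
              chromosome = rep("chr4", 1000), position = seq_len(1000))
      cl <- rbind(codedCalls(codeAlleles(f1)), codedCalls(codeAlleles(f2)))
      cd <- ancestryMosaic:::.codedAlleles(cl, ancestryMosaic:::.snpRanges(
        c(snpChromosomes(f1), snpChromosomes(f2)),
        c(snpPositions(f1), snpPositions(f2))))
      pValue(permutationTest(cd, "O", nPermutations = 50, seed = r,
                             minSnps = 50L)) <= 0.02
    }, logical(1)))
  }, numeric(1))
  expect_true(all(diff(hit) >= 0))
  expect_gt(hit[3], hit[1])
})
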