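test_that("expected covariance follows the shared-path algebra", {
  expect_equal(expectedCovariance(starGraph(0.1, 0.2))[c("A", "B"), c("A", "B")],
               matrix(c(0.1, 0, 0, 0.2), 2,
                      dimnames = list(c("A", "B"), c("A", "B"))))
  g <- populationGraph(data.frame(
    parent = c("R", "R", "I", "I", "R"),
    child  = c("C", "I", "A", "B", "O"),
    drift  = c(0.02, 0.05, 0.01, 0.03, 0)), outgroup = "O")
  expect_equal(expectedCovariance(g)["A", "B"], 0.05)
})

test_that("migration covariance matches both algebra and a drift simulation", {
  # B is a 0.7/0.3 mixture of the lineages of A (c = 0.1) and C (c = 0.2)
  g <- populationGraph(data.frame(
    parent = c("R", "R", "u", "v", "u", "R"),
    child  = c("u", "v", "A", "C", "B", "O"),
    drift  = c(0.1, 0.2, 0, 0, 0, 0)), outgroup = "O",
    migrations = data.frame(from = "C", to = "B", weight = 0.3))
  W <- expectedCovariance(g)
  expect_equal(W["A", "B"], 0.07)
  expect_equal(W["B", "C"], 0.06)
  expect_equal(W["B", "B"], 0.067)
  # Monte Carlo oracle: independent drift replicates at fixed root p = 0.5
  f <- alleleFreqs(simulateFrequencies(g, 2e5, rootDist("point", value = 0.5),
                                       seed = 31))
  emp <- crossprod(f - 0.5) / nrow(f) / 0.25   # drift units at p(1-p) = 1/4
  expect_equal(emp["A", "B"], 0.07, tolerance = 0.05)
  expect_equal(emp["B", "C"], 0.06, tolerance = 0.06)
  expect_equal(emp["B", "B"], 0.067, tolerance = 0.05)
})

test_that("expected covariance is PSD and reduces to the tree as w -> 0", {
  for (s in 1:5) {
    set.seed(s)
    phy <- ape::rtree(6, tip.label = c(paste0("t", 1:5), "O"))
    g <- phyloToGraph(phy, "O", drift = 0)
    g@branches$drift <- runif(nrow(g@branches), 0, 0.3)
    br <- g@branches$child
    mg <- data.frame(from = sample(br, 1), to = sample(br, 1), weight = 0.4)
    gm <- tryCatch(populationGraph(g@branches, "O", mg),
                   error = function(e) g)
    ev <- eigen(expectedCovariance(gm), symmetric = TRUE, only.values = TRUE)
    expect_gt(min(ev$values), -1e-10)
  }
  g <- fivePopAdmixed(1e-9)
  expect_equal(expectedCovariance(g), expectedCovariance(fivePopTree()),
               tolerance = 1e-7)
})

test_that("neighbor joining recovers noiseless and simulated topologies", {
  truth <- fivePopTree()
  W <- expectedCovariance(truth)
  tr <- treeFromCovariance(W, "O")
  expect_equal(plainRF(graphToPhylo(tr), graphToPhylo(truth)), 0)
  # invariance to population order
  perm <- sample(rownames(W))
  tr2 <- treeFromCovariance(W[perm, perm], "O")
  expect_equal(plainRF(graphToPhylo(tr2), graphToPhylo(tr)), 0)
  # 8-population simulation
  g8 <- populationGraph(data.frame(
    parent = c("R", "R", "I", "I", "K", "K", "L", "L", "J", "J", "M", "M", "R"),
    child  = c("I", "J", "K", "L", "A", "B", "C", "D", "M", "E", "G", "H", "O"),
    drift  = c(0.1, 0.12, 0.08, 0.09, 0.05, 0.06, 0.05, 0.07, 0.04, 0.05,
               0.06, 0.05, 0.01)), outgroup = "O")
  f <- simulateFrequencies(g8, 5e4, midRootDist(), seed = 32)
  cv <- blockCovariance(f, 100)
  fitTree <- treeFromCovariance(cv, "O")
  expect_equal(clusteringInfoDistance(graphToPhylo(fitTree),
                                      graphToPhylo(g8)), 0)
})

test_that("parameters are recovered exactly on noiseless input", {
  truth <- fivePopAdmixed(0.4)
  W <- expectedCovariance(truth)
  start <- truth
  start@branches$drift <- rep(0.05, nrow(start@branches))
  start@migrations$weight <- 0.2
  fit <- fitParameters(start, W, centered = FALSE)
  expect_equal(fit@graph@migrations$weight, 0.4, tolerance = 1e-6)
  ord <- match(truth@branches$child, fit@graph@branches$child)
  expect_equal(fit@graph@branches$drift[ord], truth@branches$drift,
               tolerance = 1e-6)
  expect_lt(fit@objective, 1e-12)
  expect_equal(fit@pcve, 1)
})

test_that("a vanishing migration weight reduces to the pure-tree fit", {
  W <- expectedCovariance(fivePopTree())
  tfit <- fitParameters(fivePopTree(), W, centered = TRUE)
  gsmall <- fivePopAdmixed(1e-6)
  # weight held fixed: no alternation needed, just the NNLS given w ~ 0
  obj <- ancestryMosaic:::.fitObjective(
    gsmall, as.vector(W[graphLeaves(gsmall), graphLeaves(gsmall)]),
    centered = TRUE, rowWeights = NULL)
  expect_equal(obj$ssr, tfit@objective, tolerance = 1e-8)
})

test_that("pcve is 1 at a perfect fit, 0 at the grand mean, and
           invariant to population relabeling", {
  W <- expectedCovariance(fivePopAdmixed(0.4))
  fitPerfect <- new("GraphFit", graph = fivePopAdmixed(0.4), fittedCov = W,
                    pcve = 0, nEdges = 1L, objective = 0, restartLog = 0,
                    converged = TRUE, seed = NA_integer_)
  expect_equal(pcve(fitPerfect, W), 1)
  keep <- upper.tri(W, diag = TRUE)
  Wmean <- W; Wmean[] <- mean(W[keep])
  fitMean <- fitPerfect; fitMean@fittedCov <- Wmean
  expect_equal(pcve(fitMean, W), 0)
  # relabeling: permute both estimate and model identically
  perm <- c("C", "A", "O", "B", "D")
  fitPerm <- fitPerfect; fitPerm@fittedCov <- W[perm, perm]
  expect_equal(pcve(fitPerm, W), pcve(fitPerfect, W))
  # constant estimate is flagged undefined
  expect_warning(p <- pcve(fitMean, Wmean), "undefined")
  expect_true(is.na(p))
})

test_that("the greedy search recovers a planted edge and PCVE is
           monotone in the edge count", {
  truth <- fivePopAdmixed(0.4)
  f <- simulateFrequencies(truth, 5e4, midRootDist(), seed = 33)
  cv <- blockCovariance(f, 100)
  fits <- fitAdmixtureGraphs(cv, "O", maxEdges = 2, restarts = 3, seed = 34)
  expect_length(fits, 3)
  expect_identical(fits[[1]]@nEdges, 0L)
  p <- vapply(fits, pcveValue, numeric(1))
  expect_true(all(diff(p) > -1e-6))
  expect_gt(p[2] - p[1], 0.05)
  # the first added edge links the true donor and recipient lineages
  mg <- fits[[2]]@graph@migrations
  expect_identical(mg$to, "B")
  expect_identical(mg$from, "C")
  expect_equal(mg$weight, 0.4, tolerance = 0.1)
  # null behaviour: on tree-generated data extra edges buy almost nothing
  fTree <- simulateFrequencies(fivePopTree(), 5e4, midRootDist(), seed = 35)
  fitsT <- fitAdmixtureGraphs(blockCovariance(fTree, 100), "O",
                              maxEdges = 1, restarts = 3, seed = 36)
  expect_lt(pcveValue(fitsT[[2]]) - pcveValue(fitsT[[1]]), 0.01)
})
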