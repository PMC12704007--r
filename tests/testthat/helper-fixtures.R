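# Shared fixtures: canonical study-design graphs and small builders.

# three-leaf star with an outgroup of zero drift
starGraph <- function(driftA = 0.1, driftB = 0.2) {
  populationGraph(data.frame(parent = "R", child = c("A", "B", "O"),
                             drift = c(driftA, driftB, 0)),
                  outgroup = "O")
}

# five populations (incl. outgroup): (((A,B),(C,D)),O); strong shared drift
# on I, J and the donor C so that a migration edge C -> B (w = 0.4) is
# clearly non-tree-like.  This is the one-edge admixture study design used
# throughout the recovery checks.
fivePopBranches <- function() {
  data.frame(parent = c("R", "R", "I", "I", "J", "J", "R"),
             child  = c("I", "J", "A", "B", "C", "D", "O"),
             drift  = c(0.4, 0.4, 0.02, 0.01, 0.4, 0.02, 0.01))
}

fivePopTree <- function() populationGraph(fivePopBranches(), outgroup = "O")

fivePopAdmixed <- function(w = 0.4) {
  populationGraph(fivePopBranches(), outgroup = "O",
                  migrations = data.frame(from = "C", to = "B", weight = w))
}

midRootDist <- function() rootDist("uniform", min = 0.2, max = 0.8)

# mild-drift admixed graph: cumulative drift is small enough that [0,1]
# truncation is negligible, the regime in which the linear Gaussian model
# is an exact description of the simulator
mildAdmixedGraph <- function(w = 0.4) {
  populationGraph(data.frame(
    parent = c("R", "R", "I", "I", "J", "J", "R"),
    child  = c("I", "J", "A", "B", "C", "D", "O"),
    drift  = c(0.03, 0.02, 0.02, 0.04, 0.03, 0.05, 0.01)), outgroup = "O",
    migrations = data.frame(from = "C", to = "B", weight = w))
}
sfsRootDist <- function() rootDist("beta", shape1 = 0.2, shape2 = 0.2)

# balanced eight-population tree (7 ingroup + outgroup), drift d per branch;
# tips assigns leaves to the fixed shape ((t1,t2),(t3,((t4,t5)))) layout
balancedTree <- function(tips = c("A", "B", "C", "D", "E"), d = 0.1) {
  populationGraph(data.frame(
    parent = c("R", "R", "I", "I", "J", "J", "K", "K", "R"),
    child  = c("I", "J", tips[1], tips[2], tips[3], "K", tips[4], tips[5],
               "O"),
    drift = rep(d, 9)), outgroup = "O")
}

# exchange-symmetric 50/50 admixture quartet: Y draws half its ancestry from
# the X-side lineage and half from the Z lineage; the graph is invariant
# under swapping X and Z, so topology scores 1 and 3 are equal in
# distribution.  Strong post-admixture drift on Y re-fixes alleles so the
# 0.95 coding sees them.
symmetricQuartetGraph <- function() {
  populationGraph(data.frame(
    parent = c("R", "R", "A", "A", "Mx", "Mx"),
    child  = c("O", "A", "Mx", "Z", "X", "Y"),
    drift  = c(0.4, 0.4, 0.6, 1.2, 0.6, 1.5)), outgroup = "O",
    migrations = data.frame(from = "Z", to = "Y", weight = 0.5))
}

# quick FrequencyMatrix from a plain matrix
fm <- function(freq, chrom = NULL, pos = NULL) {
  if (is.null(chrom)) chrom <- rep("chr1", nrow(freq))
  if (is.null(pos)) pos <- seq_len(nrow(freq))
  frequencyMatrix(freq, chrom, pos)
}

# random rooted tree on n leaves with an extra outgroup tip
randomRootedTree <- function(n, seed) {
  set.seed(seed)
  phy <- ape::rtree(n, tip.label = paste0("t", seq_len(n)))
  phy
}

# brute-force clustering-information distance: enumerate every injective
# partial matching of the two split sets (reference oracle, factorial cost)
bruteForceCID <- function(t1, t2) {
  ord <- sort(t1$tip.label)
  s1 <- ancestryMosaic:::treeSplits(t1, ord)
  s2 <- ancestryMosaic:::treeSplits(t2, ord)
  h <- sum(apply(s1, 2, ancestryMosaic:::.splitEntropy)) +
    sum(apply(s2, 2, ancestryMosaic:::.splitEntropy))
  k1 <- ncol(s1); k2 <- ncol(s2)
  if (k1 == 0 || k2 == 0) return(h)
  best <- 0
  recurse <- function(i, used, acc) {
    if (i > k1) { best <<- max(best, acc); return(invisible()) }
    recurse(i + 1L, used, acc)                      # leave split i unmatched
    for (j in seq_len(k2)) if (!used[j]) {
      used[j] <- TRUE
      recurse(i + 1L, used,
              acc + ancestryMosaic:::.splitMutualInfo(s1[, i], s2[, j]))
      used[j] <- FALSE
    }
  }
  recurse(1L, rep(FALSE, k2), 0)
  h - 2 * best
}
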