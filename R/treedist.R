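# Per-chromosome tree estimation, generalized (clustering-information)
# Robinson-Foulds distances, and the SNP-permutation test for
# among-chromosome tree heterogeneity.

# internal: coded calls -> numeric (ALT = 1, REF = 0, N = NA)
.codedNumeric <- function(calls) {
  x <- matrix(NA_real_, nrow(calls), ncol(calls), dimnames = dimnames(calls))
  x[calls == "ALT"] <- 1
  x[calls == "REF"] <- 0
  x
}

# internal: pairwise Hamming distance on a 0/1/NA matrix (SNPs x pops),
# N excluded pairwise
.codedDistance <- function(x) {
  ones <- !is.na(x) & x == 1
  zeros <- !is.na(x) & x == 0
  pres <- !is.na(x)
  storage.mode(ones) <- storage.mode(zeros) <- storage.mode(pres) <- "double"
  diff <- crossprod(ones, zeros)
  diff <- diff + t(diff)
  den <- crossprod(pres)
  if (any(den == 0))
    stop("estimation error: a population pair has no jointly coded SNPs")
  d <- diff / den
  dimnames(d) <- list(colnames(x), colnames(x))
  d
}

#' Estimate a chromosome tree from coded alleles
#'
#' Pairwise population distances are the proportion of jointly coded
#' (non-`N`) SNPs at which two populations' coded alleles differ; the tree
#' is built by neighbor joining and rooted on the outgroup.  This is a
#' deterministic distance-based estimator, consistent on tree-like data;
#' the permutation machinery below is agnostic to the estimator.
#'
#' @param coded a [CodedAlleles-class] (one chromosome, or any SNP subset).
#' @param outgroup population used to root the tree.
#' @param minSnps refuse estimation below this many usable SNPs (SNPs coded
#'   in at least two populations; default 100).
#' @return a rooted `phylo` (topology only; branch lengths are the NJ
#'   estimates and are ignored by the distance computations).
#' @export
chromosomeTree <- function(coded, outgroup, minSnps = 100L) {
  .treeFromCalls(codedCalls(coded), outgroup, minSnps)
}

# matrix-level worker shared with the permutation machinery (which re-runs
# the estimator hundreds of times and must avoid container overhead)
.treeFromCalls <- function(cl, outgroup, minSnps) {
  if (ncol(cl) < 4L) stop("need >= 4 populations")
  if (!(outgroup %in% colnames(cl)))
    stop("input error: outgroup absent from the coded matrix")
  x <- .codedNumeric(cl)
  usable <- rowSums(!is.na(x)) >= 2L
  if (sum(usable) < minSnps)
    stop(sprintf("estimation error: %d usable SNPs < floor of %d",
                 sum(usable), minSnps))
  d <- .codedDistance(x[usable, , drop = FALSE])
  rootOnOutgroup(ape::nj(d), outgroup)
}

# --- splits and information-theoretic distance ------------------------------

# internal: nontrivial splits of a tree as a logical matrix (leaves x splits)
# in canonical leaf order; complements deduplicated; column normalized so the
# first leaf is FALSE.
treeSplits <- function(phy, leafOrder = NULL) {
  if (is.null(leafOrder)) leafOrder <- sort(phy$tip.label)
  n <- length(leafOrder)
  parts <- ape::prop.part(ape::unroot(phy))
  labs <- attr(parts, "labels")
  cols <- list()
  seen <- character(0)
  for (p in parts) {
    side <- leafOrder %in% labs[p]
    k <- sum(side)
    if (k < 2L || k > n - 2L) next
    if (side[1]) side <- !side
    key <- paste(side, collapse = "")
    if (key %in% seen) next
    seen <- c(seen, key)
    cols[[length(cols) + 1L]] <- side
  }
  m <- if (length(cols)) do.call(cbind, cols)
       else matrix(logical(0), nrow = n, ncol = 0)
  rownames(m) <- leafOrder
  m
}

.splitEntropy <- function(split) {
  p <- mean(split)
  if (p <= 0 || p >= 1) return(0)
  -(p * log2(p) + (1 - p) * log2(1 - p))
}

# mutual clustering information (bits) between two bipartitions
.splitMutualInfo <- function(s1, s2) {
  n <- length(s1)
  n11 <- sum(s1 & s2); n10 <- sum(s1) - n11
  n01 <- sum(s2) - n11; n00 <- n - n11 - n10 - n01
  p <- c(n11, n10, n01, n00) / n
  a <- (n11 + n10) / n; b <- (n11 + n01) / n
  q <- c(a * b, a * (1 - b), (1 - a) * b, (1 - a) * (1 - b))
  keep <- p > 0
  sum(p[keep] * log2(p[keep] / q[keep]))
}

# maximum-weight matching of splits by subset dynamic programming; returns
# the summed matched mutual information.  Exponential in the smaller split
# count, intended for the <= ~12 nontrivial splits of the population trees
# this package targets.
.maxMatching <- function(wmat) {
  k1 <- nrow(wmat); k2 <- ncol(wmat)
  if (k1 == 0L || k2 == 0L) return(0)
  if (k1 > k2) wmat <- t(wmat)
  k1 <- nrow(wmat); k2 <- ncol(wmat)
  nStates <- bitwShiftL(1L, k2)
  f <- numeric(nStates)          # best over first 0 rows
  for (i in seq_len(k1)) {
    g <- f
    for (state in 0:(nStates - 1L)) {
      base <- f[state + 1L]
      for (j in seq_len(k2)) {
        bit <- bitwShiftL(1L, j - 1L)
        if (bitwAnd(state, bit) == 0L) {
          cand <- base + wmat[i, j]
          idx <- state + bit + 1L
          if (cand > g[idx]) g[idx] <- cand
        }
      }
    }
    # allow leaving row i unmatched: g already >= f via base copy
    f <- pmax(f, g)
  }
  max(f)
}

#' Generalized Robinson-Foulds (clustering-information) distance
#'
#' Each nontrivial split is treated as a two-cluster partition of the leaf
#' set with entropy `H` (bits); splits of the two trees are matched one to
#' one so as to maximize the summed mutual clustering information, and the
#' distance is the total split entropy of both trees minus twice the matched
#' shared information.  Zero if and only if the split sets coincide.
#'
#' @param t1,t2 rooted or unrooted `phylo` objects on the same leaf set.
#' @return non-negative distance in bits.
#' @seealso [plainRF()], [permutationTest()]
#' @export
clusteringInfoDistance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("input error: trees must share one leaf set")
  ord <- sort(t1$tip.label)
  s1 <- treeSplits(t1, ord)
  s2 <- treeSplits(t2, ord)
  h1 <- sum(apply(s1, 2, .splitEntropy))
  h2 <- sum(apply(s2, 2, .splitEntropy))
  if (ncol(s1) == 0L || ncol(s2) == 0L) return(h1 + h2)
  wmat <- matrix(0, ncol(s1), ncol(s2))
  for (i in seq_len(ncol(s1))) for (j in seq_len(ncol(s2)))
    wmat[i, j] <- .splitMutualInfo(s1[, i], s2[, j])
  h1 + h2 - 2 * .maxMatching(wmat)
}

#' Plain Robinson-Foulds distance
#'
#' Number of nontrivial splits present in exactly one of the two trees.
#'
#' @param t1,t2 `phylo` objects on the same leaf set.
#' @return non-negative integer count.
#' @export
plainRF <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("input error: trees must share one leaf set")
  ord <- sort(t1$tip.label)
  k1 <- apply(treeSplits(t1, ord), 2, paste, collapse = "")
  k2 <- apply(treeSplits(t2, ord), 2, paste, collapse = "")
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

# internal: mean pairwise clustering-information distance over a tree list,
# plus the full matrix
.pairwiseCID <- function(trees) {
  k <- length(trees)
  d <- matrix(0, k, k, dimnames = list(names(trees), names(trees)))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k)
    d[i, j] <- d[j, i] <- clusteringInfoDistance(trees[[i]], trees[[j]])
  d
}

#' SNP-permutation test for among-chromosome tree heterogeneity
#'
#' Estimates a tree per chromosome, computes the mean pairwise
#' clustering-information distance, and compares it with a null in which
#' SNPs are randomly reassigned to chromosomes (preserving per-chromosome
#' SNP counts) and all trees are re-estimated.  The P-value uses the +1
#' correction, `P = (1 + #\{null >= observed\}) / (1 + n)`, so `P` is never
#' zero and its smallest attainable value with the default 50 permutations
#' is `1/51`, consistent with reporting bounds such as `P < 0.02`.
#'
#' @param coded a [CodedAlleles-class] spanning >= 2 chromosomes.
#' @param outgroup population used to root every tree.
#' @param nPermutations number of permutations (default 50).
#' @param seed integer seed.
#' @param minSnps per-chromosome usable-SNP floor passed to
#'   [chromosomeTree()]; a permutation leaving a chromosome below the floor
#'   or otherwise inestimable is rejected and redrawn (messaged).
#' @return a [DistanceResult-class].
#' @export
permutationTest <- function(coded, outgroup, nPermutations = 50L, seed = 1L,
                            minSnps = 100L) {
  cl <- codedCalls(coded)
  chrom <- snpChromosomes(coded)
  chroms <- unique(chrom)
  if (length(chroms) < 2L) stop("need >= 2 chromosomes")
  counts <- table(factor(chrom, levels = chroms))
  makeTrees <- function(assignment) {
    lapply(setNames(chroms, chroms), function(ch)
      .treeFromCalls(cl[assignment == ch, , drop = FALSE], outgroup,
                     minSnps))
  }
  trees <- makeTrees(chrom)
  dmat <- .pairwiseCID(trees)
  observed <- mean(dmat[upper.tri(dmat)])
  set.seed(seed)
  nullMeans <- numeric(nPermutations)
  for (b in seq_len(nPermutations)) {
    for (attempt in seq_len(100L)) {
      perm <- sample(chrom)
      stopifnot(identical(table(factor(perm, levels = chroms)), counts))
      pt <- tryCatch(makeTrees(perm), error = function(e) NULL)
      if (!is.null(pt)) break
      message("permutation ", b, " redrawn (chromosome under the SNP floor)")
    }
    if (is.null(pt))
      stop("estimation error: could not draw a valid permutation")
    pd <- .pairwiseCID(pt)
    nullMeans[b] <- mean(pd[upper.tri(pd)])
  }
  p <- (1 + sum(nullMeans >= observed)) / (1 + nPermutations)
  new("DistanceResult", distances = dmat, trees = trees,
      observed = observed, nullMeans = nullMeans, pValue = p,
      nPermutations = as.integer(nPermutations), seed = as.integer(seed))
}
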