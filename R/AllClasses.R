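#' @import methods
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowRanges rowData
#' @importFrom GenomicRanges GRanges seqnames start
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols DataFrame
#' @importFrom stats var sd cor optimize rnorm rbinom rpois runif rbeta pt qt
#'   setNames complete.cases lm cor.test na.omit quantile
#' @importFrom utils head tail read.table write.table
NULL

# ---------------------------------------------------------------------------
# PopulationGraph: rooted tree with drift-length branches plus weighted
# migration edges.  Branches are identified by their child node; a migration
# edge attaches the midpoint of a donor branch to a destination node.
# ---------------------------------------------------------------------------

#' PopulationGraph: an admixture graph over populations
#'
#' A rooted population tree whose branches carry non-negative drift parameters
#' (dimensionless; the variance of allele-frequency change along a branch is
#' `c * p * (1 - p)` with `p` the parent frequency), augmented with migration
#' (admixture) edges.  Each migration edge connects the midpoint of a donor
#' branch to a destination node and carries a weight `w` in (0, 1): the
#' destination's allele frequency is `w` times the donor-midpoint frequency
#' plus `1 - w` times its tree parent's frequency, mixed before the drift on
#' the destination's own branch.
#'
#' @slot branches data.frame with columns `parent`, `child` (node
#'   identifiers) and `drift` (numeric, >= 0).  Branches are identified by
#'   their child node.
#' @slot migrations data.frame with columns `from` (child identifier of the
#'   donor branch), `to` (destination node) and `weight` (in (0, 1)).
#' @slot root character, the root node identifier.
#' @slot outgroup character, a leaf used for rooting and allele polarization.
#'
#' @seealso [populationGraph()], [expectedCovariance()],
#'   [simulateFrequencies()]
#' @export
setClass("PopulationGraph",
  representation(
    branches   = "data.frame",
    migrations = "data.frame",
    root       = "character",
    outgroup   = "character"
  )
)

setValidity("PopulationGraph", function(object) {
  br <- object@branches
  if (!all(c("parent", "child", "drift") %in% names(br)))
    return("branches must have columns parent, child, drift")
  if (anyDuplicated(br$child))
    return("each node may have at most one tree parent")
  nodes <- union(br$parent, br$child)
  roots <- setdiff(br$parent, br$child)
  if (length(roots) != 1L)
    return(sprintf("graph must have exactly one root (found %d)",
                   length(roots)))
  if (!identical(object@root, roots))
    return("root slot does not match the branch table")
  if (any(br$drift < 0)) return("drift values must be non-negative")
  # connectivity: every node reaches the root
  parent <- setNames(br$parent, br$child)
  for (v in br$child) {
    seen <- character(0)
    while (v %in% names(parent)) {
      if (v %in% seen) return("branch table contains a cycle")
      seen <- c(seen, v)
      v <- parent[[v]]
    }
    if (!identical(v, roots)) return("branch table is not a connected tree")
  }
  mg <- object@migrations
  if (nrow(mg)) {
    if (!all(c("from", "to", "weight") %in% names(mg)))
      return("migrations must have columns from, to, weight")
    if (!all(mg$from %in% br$child))
      return("migration donor branches must be branches of the tree")
    if (!all(mg$to %in% br$child))
      return("migration destinations must be non-root nodes")
    if (any(mg$weight <= 0 | mg$weight >= 1))
      return("migration weights must lie strictly in (0, 1)")
    tot <- tapply(mg$weight, mg$to, sum)
    if (any(tot >= 1))
      return("total migration weight into a node must be < 1")
    ok <- tryCatch({ graphEvents(object); TRUE },
                   error = function(e) conditionMessage(e))
    if (!isTRUE(ok)) return(ok)
  }
  lv <- setdiff(br$child, br$parent)
  if (length(object@outgroup) != 1L || !(object@outgroup %in% lv))
    return("outgroup must be a single leaf of the tree")
  TRUE
})

# ---------------------------------------------------------------------------
# SummarizedExperiment-backed SNP x population containers
# ---------------------------------------------------------------------------

#' Pooled allele counts (SNPs x populations)
#'
#' Read counts supporting the reference and alternate allele for each SNP and
#' population pool, stored as a [SummarizedExperiment::RangedSummarizedExperiment]
#' with assays `ref` and `alt` and SNP coordinates in `rowRanges`.  Sites with
#' zero total depth in a pool are the container's explicit missing state.
#'
#' @seealso [alleleCounts()], [simulatePoolseq()], [estimateFrequencies()]
#' @export
setClass("AlleleCounts", contains = "RangedSummarizedExperiment")

#' Population allele-frequency matrix (SNPs x populations)
#'
#' Alternate-allele frequencies in `[0, 1]` (or `NA` where missing) with SNP
#' coordinates, stored as a `RangedSummarizedExperiment` with a single assay
#' `freq`.
#'
#' @seealso [frequencyMatrix()], [simulateFrequencies()], [blockCovariance()]
#' @export
setClass("FrequencyMatrix", contains = "RangedSummarizedExperiment")

#' Discrete coded alleles (SNPs x populations)
#'
#' Per-population SNP calls over `"REF"`, `"ALT"`, `"N"` produced by
#' [codeAlleles()]: a population is coded with its common allele when that
#' allele's frequency reaches the threshold and as ambiguous (`"N"`)
#' otherwise.  Stored as a `RangedSummarizedExperiment` with assay `calls`.
#'
#' @seealso [codeAlleles()], [chromosomeTree()], [snpVote()]
#' @export
setClass("CodedAlleles", contains = "RangedSummarizedExperiment")

.validSnpSE <- function(object, assayNames) {
  if (!all(assayNames %in% SummarizedExperiment::assayNames(object)))
    return(sprintf("assays %s required", paste(assayNames, collapse = ", ")))
  if (is.null(colnames(object))) return("population (column) names required")
  pos <- GenomicRanges::start(SummarizedExperiment::rowRanges(object))
  chr <- as.character(GenomicRanges::seqnames(
    SummarizedExperiment::rowRanges(object)))
  byChr <- split(pos, chr)
  if (any(vapply(byChr, function(p) any(diff(p) <= 0), logical(1))))
    return("positions must be strictly increasing within each chromosome")
  TRUE
}

setValidity("AlleleCounts", function(object) {
  ok <- .validSnpSE(object, c("ref", "alt"))
  if (!isTRUE(ok)) return(ok)
  r <- SummarizedExperiment::assay(object, "ref")
  a <- SummarizedExperiment::assay(object, "alt")
  if (any(r < 0, na.rm = TRUE) || any(a < 0, na.rm = TRUE))
    return("read counts must be non-negative")
  TRUE
})

setValidity("FrequencyMatrix", function(object) {
  ok <- .validSnpSE(object, "freq")
  if (!isTRUE(ok)) return(ok)
  f <- SummarizedExperiment::assay(object, "freq")
  if (any(f < 0 | f > 1, na.rm = TRUE))
    return("frequencies must lie in [0, 1]")
  TRUE
})

setValidity("CodedAlleles", function(object) {
  ok <- .validSnpSE(object, "calls")
  if (!isTRUE(ok)) return(ok)
  cl <- SummarizedExperiment::assay(object, "calls")
  if (!all(cl %in% c("REF", "ALT", "N")))
    return("calls must be REF, ALT or N")
  TRUE
})

# ---------------------------------------------------------------------------
# Result containers
# ---------------------------------------------------------------------------

#' Block-resampled covariance estimate
#'
#' Population allele-frequency covariance (frequencies centered by the
#' across-population mean at each SNP) with block-resampling standard errors.
#'
#' @slot matrix symmetric populations x populations covariance estimate.
#' @slot se matching matrix of standard errors (sd over blocks / sqrt(blocks)).
#' @slot blockSize SNPs per block.
#' @slot nBlocks number of complete blocks used.
#' @seealso [blockCovariance()]
#' @export
setClass("CovarianceEstimate",
  representation(matrix = "matrix", se = "matrix",
                 blockSize = "integer", nBlocks = "integer"))

setValidity("CovarianceEstimate", function(object) {
  m <- object@matrix
  if (!isSymmetric(unname(m), tol = 1e-8)) return("matrix must be symmetric")
  if (!identical(dim(m), dim(object@se))) return("se dimensions must match")
  if (any(object@se < 0)) return("standard errors must be non-negative")
  if (object@blockSize < 1L) return("blockSize must be >= 1")
  TRUE
})

#' Fitted admixture graph
#'
#' Result of fitting a [PopulationGraph-class] (drift values and migration
#' weights) to a [CovarianceEstimate-class] by least squares.
#'
#' @slot graph the fitted [PopulationGraph-class].
#' @slot fittedCov expected covariance of the fitted graph, on the same
#'   (centered) scale as the estimate it was fitted to.
#' @slot pcve proportion of covariance explained, in `[0, 1]`.
#' @slot nEdges number of migration edges.
#' @slot objective residual sum of squares at the optimum.
#' @slot restartLog numeric vector of per-restart objective values.
#' @slot converged logical, FALSE if the alternating fit hit its iteration cap.
#' @slot seed integer seed used for stochastic restarts (NA if none).
#' @seealso [fitAdmixtureGraphs()], [fitParameters()], [pcve()]
#' @export
setClass("GraphFit",
  representation(graph = "PopulationGraph", fittedCov = "matrix",
                 pcve = "numeric", nEdges = "integer", objective = "numeric",
                 restartLog = "numeric", converged = "logical",
                 seed = "integer"))

setValidity("GraphFit", function(object) {
  if (length(object@pcve) != 1L || is.na(object@pcve) ||
      object@pcve < 0 || object@pcve > 1)
    return("pcve must be a proportion in [0, 1]")
  if (object@nEdges != nrow(object@graph@migrations))
    return("nEdges must equal the number of migration edges in graph")
  if (!isSymmetric(unname(object@fittedCov), tol = 1e-8))
    return("fittedCov must be symmetric")
  TRUE
})

#' Among-chromosome tree-heterogeneity test result
#'
#' Pairwise generalized Robinson-Foulds (clustering-information) distances
#' among per-chromosome trees and the SNP-permutation null for their mean.
#'
#' @slot distances symmetric chromosomes x chromosomes distance matrix (bits).
#' @slot trees list of rooted `phylo` trees, one per chromosome.
#' @slot observed observed mean pairwise distance.
#' @slot nullMeans mean pairwise distance for each permutation.
#' @slot pValue `(1 + #\{null >= observed\}) / (1 + n_permutations)`.
#' @slot nPermutations number of permutations.
#' @slot seed integer seed.
#' @seealso [permutationTest()], [clusteringInfoDistance()]
#' @export
setClass("DistanceResult",
  representation(distances = "matrix", trees = "list", observed = "numeric",
                 nullMeans = "numeric", pValue = "numeric",
                 nPermutations = "integer", seed = "integer"))

setValidity("DistanceResult", function(object) {
  d <- object@distances
  if (!isSymmetric(unname(d), tol = 1e-8)) return("distances must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) return("distance diagonal must be zero")
  if (length(object@nullMeans) != object@nPermutations)
    return("one null mean per permutation required")
  p <- object@pValue
  if (p <= 0 || p > 1) return("pValue must lie in (0, 1]")
  TRUE
})

#' Additive genetic variance partition
#'
#' Per-chromosome additive genetic variance `Va_c = sum_j 2 p_j (1 - p_j)
#' beta_j^2` and the chromosome proportions of the total.
#'
#' @slot vaByChromosome named numeric, Va per chromosome (phenotype variance
#'   units).
#' @slot totalVa total Va.
#' @slot proportions named numeric, summing to 1.
#' @slot zFractionOfGenome proportion of the genome (by size) on the Z
#'   chromosome, `NA` when sizes were not supplied.
#' @seealso [partitionVa()]
#' @export
setClass("VaPartition",
  representation(vaByChromosome = "numeric", totalVa = "numeric",
                 proportions = "numeric", zFractionOfGenome = "numeric"))

setValidity("VaPartition", function(object) {
  if (any(object@vaByChromosome < 0)) return("Va must be non-negative")
  if (object@totalVa > 0 &&
      abs(sum(object@proportions) - 1) > 1e-9)
    return("proportions must sum to 1")
  TRUE
})

#' Genome simulation configuration
#'
#' Chromosome layout and pool-sequencing parameters for
#' [simulateGenomeDataset()].  Every chromosome is assigned a
#' [PopulationGraph-class]; chromosome classes (e.g. autosomes vs the Z) can
#' be given different graphs.
#'
#' @slot chromosomeSizes named numeric, chromosome sizes in base pairs.
#' @slot snpsPerChromosome named integer, SNPs simulated per chromosome.
#' @slot graphAssignment named list of [PopulationGraph-class], one per
#'   chromosome, all over the same leaf set.
#' @slot rootFreqDist root allele-frequency distribution spec (see
#'   [simulateFrequencies()]).
#' @slot poolDepth mean reads per SNP per population.
#' @slot poolSize diploid individuals per pool.
#' @seealso [simulationConfig()], [simulateGenomeDataset()]
#' @export
setClass("SimulationConfig",
  representation(chromosomeSizes = "numeric", snpsPerChromosome = "integer",
                 graphAssignment = "list", rootFreqDist = "list",
                 poolDepth = "numeric", poolSize = "integer"))

setValidity("SimulationConfig", function(object) {
  ch <- names(object@chromosomeSizes)
  if (is.null(ch) || anyDuplicated(ch))
    return("chromosome sizes must have unique names")
  if (any(object@chromosomeSizes <= 0)) return("chromosome sizes must be positive")
  if (!identical(sort(ch), sort(names(object@snpsPerChromosome))) ||
      !identical(sort(ch), sort(names(object@graphAssignment))))
    return("sizes, SNP counts and graph assignment must cover the same chromosomes")
  if (any(object@snpsPerChromosome < 1L)) return("SNP counts must be positive")
  if (!all(vapply(object@graphAssignment, is, logical(1), "PopulationGraph")))
    return("graphAssignment must contain PopulationGraph objects")
  leaves <- lapply(object@graphAssignment, graphLeaves)
  if (length(unique(lapply(leaves, sort))) != 1L)
    return("all chromosome graphs must share one leaf (population) set")
  if (object@poolDepth <= 0) return("poolDepth must be positive")
  if (object@poolSize < 1L) return("poolSize must be >= 1")
  TRUE
})
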