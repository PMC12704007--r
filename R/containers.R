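# Constructors and accessors for the SNP x population containers.

.snpRanges <- function(chromosome, position) {
  GenomicRanges::GRanges(seqnames = chromosome,
                         ranges = IRanges::IRanges(start = position, width = 1))
}

.orderSnps <- function(chromosome, position) {
  order(factor(chromosome, levels = unique(chromosome)), position)
}

#' Construct an AlleleCounts object
#'
#' @param ref,alt integer matrices (SNPs x populations) of reference and
#'   alternate read counts.  Pools with zero total depth at a site are the
#'   explicit missing state.
#' @param chromosome,position SNP coordinates (1-based); rows are sorted by
#'   chromosome and position.
#' @param populations column (population) names; defaults to `colnames(ref)`.
#' @return An [AlleleCounts-class].
#' @export
alleleCounts <- function(ref, alt, chromosome, position, populations = NULL) {
  if (!is.null(populations)) colnames(ref) <- colnames(alt) <- populations
  o <- .orderSnps(chromosome, position)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(ref = ref[o, , drop = FALSE], alt = alt[o, , drop = FALSE]),
    rowRanges = .snpRanges(chromosome[o], position[o]))
  new("AlleleCounts", se)
}

#' Construct a FrequencyMatrix
#'
#' @param freq numeric matrix (SNPs x populations) of alternate-allele
#'   frequencies in `[0, 1]`, `NA` for missing.
#' @param chromosome,position SNP coordinates (1-based).
#' @param populations optional column names.
#' @return A [FrequencyMatrix-class].
#' @export
frequencyMatrix <- function(freq, chromosome, position, populations = NULL) {
  if (!is.null(populations)) colnames(freq) <- populations
  o <- .orderSnps(chromosome, position)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(freq = freq[o, , drop = FALSE]),
    rowRanges = .snpRanges(chromosome[o], position[o]))
  new("FrequencyMatrix", se)
}

.codedAlleles <- function(calls, rowRanges) {
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(calls = calls), rowRanges = rowRanges)
  new("CodedAlleles", se)
}

#' Population labels of a SNP container
#' @param x an [AlleleCounts-class], [FrequencyMatrix-class] or
#'   [CodedAlleles-class].
#' @return character vector of population identifiers.
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))

#' @rdname populations
#' @export
setMethod("populations", "RangedSummarizedExperiment",
          function(x) colnames(x))

#' Chromosome label per SNP
#' @param x a SNP container.
#' @return character vector, one entry per SNP.
#' @export
snpChromosomes <- function(x)
  as.character(GenomicRanges::seqnames(SummarizedExperiment::rowRanges(x)))

#' Position per SNP (1-based)
#' @param x a SNP container.
#' @return integer vector.
#' @export
snpPositions <- function(x)
  GenomicRanges::start(SummarizedExperiment::rowRanges(x))

#' Assay accessors
#' @param x an [AlleleCounts-class].
#' @return integer matrix of reference read counts.
#' @export
refCounts <- function(x) SummarizedExperiment::assay(x, "ref")

#' @rdname refCounts
#' @return integer matrix of alternate read counts.
#' @export
altCounts <- function(x) SummarizedExperiment::assay(x, "alt")

#' Allele-frequency assay of a FrequencyMatrix
#' @param x a [FrequencyMatrix-class].
#' @return numeric matrix (SNPs x populations) with `NA` for missing.
#' @export
alleleFreqs <- function(x) SummarizedExperiment::assay(x, "freq")

#' Coded-call assay of a CodedAlleles object
#' @param x a [CodedAlleles-class].
#' @return character matrix over `"REF"`, `"ALT"`, `"N"`.
#' @export
codedCalls <- function(x) SummarizedExperiment::assay(x, "calls")

# ---------------------------------------------------------------------------

#' @describeIn blockCovariance covariance point estimate
#' @param x a [CovarianceEstimate-class].
#' @export
covMatrix <- function(x) x@matrix

#' @describeIn blockCovariance block-resampling standard errors
#' @export
covSE <- function(x) x@se

setMethod("show", "CovarianceEstimate", function(object) {
  cat(sprintf(
    "CovarianceEstimate: %d populations, %d blocks of %d SNPs\n",
    nrow(object@matrix), object@nBlocks, object@blockSize))
  cat("  mean |cov| =", format(mean(abs(object@matrix)), digits = 4),
      " mean se =", format(mean(object@se), digits = 4), "\n")
})

#' @describeIn fitAdmixtureGraphs fitted graph accessor
#' @param x a [GraphFit-class].
#' @export
fittedGraph <- function(x) x@graph

#' Proportion of covariance explained by a fit
#' @param x a [GraphFit-class].
#' @return numeric in `[0, 1]`.
#' @export
pcveValue <- function(x) x@pcve

setMethod("show", "GraphFit", function(object) {
  cat(sprintf("GraphFit: %d migration edge(s), PCVE = %.4f, SSR = %.3g\n",
              object@nEdges, object@pcve, object@objective))
  if (!object@converged) cat("  (alternating fit hit its iteration cap)\n")
})

setMethod("show", "DistanceResult", function(object) {
  cat(sprintf(
    "DistanceResult: %d chromosomes, %d permutations\n",
    nrow(object@distances), object@nPermutations))
  cat(sprintf("  observed mean distance = %.3f bits; null mean = %.3f (range %.3f-%.3f)\n",
              object@observed, mean(object@nullMeans),
              min(object@nullMeans), max(object@nullMeans)))
  cat(sprintf("  P = %.4g\n", object@pValue))
})

#' @describeIn permutationTest permutation P-value accessor
#' @param x a [DistanceResult-class].
#' @export
pValue <- function(x) x@pValue

#' @describeIn permutationTest per-permutation null means
#' @export
nullMeans <- function(x) x@nullMeans

#' @describeIn permutationTest observed mean pairwise distance
#' @export
observedDistance <- function(x) x@observed

#' @describeIn permutationTest pairwise chromosome distance matrix
#' @export
distanceMatrix <- function(x) x@distances

#' @describeIn partitionVa per-chromosome Va proportions
#' @param x a [VaPartition-class].
#' @export
vaProportions <- function(x) x@proportions

#' @describeIn partitionVa per-chromosome Va values
#' @export
vaByChromosome <- function(x) x@vaByChromosome

setMethod("show", "VaPartition", function(object) {
  cat(sprintf("VaPartition: total Va = %.4g over %d chromosomes\n",
              object@totalVa, length(object@vaByChromosome)))
  p <- sort(object@proportions, decreasing = TRUE)
  cat("  top proportions:",
      paste(sprintf("%s=%.3f", names(head(p, 4)), head(p, 4)),
            collapse = ", "), "\n")
  if (!is.na(object@zFractionOfGenome))
    cat(sprintf("  Z fraction of genome by size: %.3f\n",
                object@zFractionOfGenome))
})
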