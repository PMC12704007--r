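# Allele-frequency estimation, block-resampled covariance, PCA and the
# discrete allele coding used by the tree / topology analyses.

#' Estimate pool allele frequencies from read counts
#'
#' `freq = alt / (ref + alt)`; sites with depth below `minDepth` in a
#' population are marked missing for that population.  SNPs missing in every
#' population are retained (flagged via the `allMissing` row metadata column).
#'
#' @param counts an [AlleleCounts-class].
#' @param minDepth minimum reads required to call a frequency (>= 1).
#' @return A [FrequencyMatrix-class]; `rowData()$allMissing` flags SNPs with
#'   no callable population.
#' @examples
#' ac <- alleleCounts(ref = cbind(P1 = 3L), alt = cbind(P1 = 7L),
#'                    chromosome = "chr1", position = 1L)
#' alleleFreqs(estimateFrequencies(ac))  # 0.7
#' @export
estimateFrequencies <- function(counts, minDepth = 1L) {
  stopifnot(minDepth >= 1)
  r <- refCounts(counts)
  a <- altCounts(counts)
  d <- r + a
  f <- a / d
  f[d < minDepth] <- NA_real_
  fm <- frequencyMatrix(f, snpChromosomes(counts), snpPositions(counts),
                        populations = populations(counts))
  SummarizedExperiment::rowData(fm)$allMissing <-
    rowSums(!is.na(alleleFreqs(fm))) == 0L
  fm
}

#' Block-resampled population allele-frequency covariance
#'
#' At each SNP, frequencies are centered by the across-population mean; the
#' covariance of the centered population frequencies is computed within
#' consecutive blocks of `blockSize` SNPs (blocks never span chromosomes; a
#' trailing partial block is dropped, preserving linkage structure within
#' blocks).  The point estimate is the mean over blocks and the standard
#' error the standard deviation over blocks divided by `sqrt(nBlocks)`.
#' Missing entries are handled pairwise-complete.
#'
#' @param freqs a [FrequencyMatrix-class].
#' @param blockSize SNPs per block (default 100).
#' @return A [CovarianceEstimate-class].
#' @export
blockCovariance <- function(freqs, blockSize = 100L) {
  f <- alleleFreqs(freqs)
  npop <- ncol(f)
  chrom <- snpChromosomes(freqs)
  y <- f - rowMeans(f, na.rm = TRUE)
  idxByChr <- split(seq_len(nrow(f)), factor(chrom, levels = unique(chrom)))
  blocks <- list()
  for (idx in idxByChr) {
    nb <- length(idx) %/% blockSize
    if (nb >= 1L)
      blocks <- c(blocks, split(idx[seq_len(nb * blockSize)],
                                rep(seq_len(nb), each = blockSize)))
  }
  nBlocks <- length(blocks)
  if (nBlocks < 2L)
    stop("estimation error: fewer than 2 complete blocks of SNPs")
  acc <- array(NA_real_, dim = c(npop, npop, nBlocks))
  for (b in seq_len(nBlocks)) {
    yb <- y[blocks[[b]], , drop = FALSE]
    pres <- !is.na(yb)
    yb0 <- yb; yb0[!pres] <- 0
    num <- crossprod(yb0)              # sum of pairwise products
    den <- crossprod(pres)             # pairwise-complete counts
    acc[, , b] <- num / den
  }
  est <- apply(acc, c(1, 2), mean, na.rm = TRUE)
  se <- apply(acc, c(1, 2), function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2L) return(NA_real_)
    sd(v) / sqrt(length(v))
  })
  dimnames(est) <- dimnames(se) <- list(colnames(f), colnames(f))
  est <- (est + t(est)) / 2
  new("CovarianceEstimate", matrix = est, se = se,
      blockSize = as.integer(blockSize), nBlocks = as.integer(nBlocks))
}

#' Principal components of the population allele-frequency matrix
#'
#' Singular value decomposition of the centered, but not standardized,
#' population x SNP frequency matrix (each SNP centered across populations;
#' no scaling to unit variance).  Missing entries are imputed by the SNP
#' mean before decomposition (a message reports how many).
#'
#' @param freqs a [FrequencyMatrix-class].
#' @param exclude populations to drop before the PCA (e.g. the outgroup).
#' @return list with `scores` (populations x PCs), `varianceFraction`
#'   (summing to 1), `loadings` (SNPs x PCs) and `sdev`.
#' @export
pcaScores <- function(freqs, exclude = character(0)) {
  f <- alleleFreqs(freqs)
  keep <- setdiff(colnames(f), exclude)
  if (length(keep) < 2L) stop("need at least 2 populations after exclusion")
  X <- t(f[, keep, drop = FALSE])        # populations x SNPs
  nmiss <- sum(is.na(X))
  if (nmiss > 0) {
    message("pcaScores: imputing ", nmiss, " missing entries by SNP means")
    mu <- colMeans(X, na.rm = TRUE)
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- mu[idx[, 2]]
  }
  X <- scale(X, center = TRUE, scale = FALSE)
  sv <- svd(X)
  npc <- min(dim(X))
  scores <- sv$u[, seq_len(npc), drop = FALSE] %*%
    diag(sv$d[seq_len(npc)], npc)
  dimnames(scores) <- list(keep, paste0("PC", seq_len(npc)))
  varfrac <- sv$d[seq_len(npc)]^2 / sum(sv$d^2)
  loadings <- sv$v[, seq_len(npc), drop = FALSE]
  colnames(loadings) <- paste0("PC", seq_len(npc))
  list(scores = scores, varianceFraction = varfrac,
       loadings = loadings, sdev = sv$d[seq_len(npc)] / sqrt(max(1, nrow(X) - 1)))
}

#' Code SNPs by the common allele within populations
#'
#' A population is coded `ALT` when the alternate-allele frequency is at or
#' above `threshold`, `REF` when at or below `1 - threshold`, and ambiguous
#' (`N`) otherwise; missing frequencies are `N`.  The comparison is `>=`
#' (configurable threshold, default 0.95).
#'
#' @param freqs a [FrequencyMatrix-class].
#' @param threshold common-allele frequency threshold, in (0.5, 1].
#' @return A [CodedAlleles-class].
#' @examples
#' fm <- frequencyMatrix(cbind(P1 = c(0.97, 0.5, 0.03)),
#'                       chromosome = rep("chr1", 3), position = 1:3)
#' codedCalls(codeAlleles(fm))  # ALT, N, REF
#' @export
codeAlleles <- function(freqs, threshold = 0.95) {
  stopifnot(threshold > 0.5, threshold <= 1)
  f <- alleleFreqs(freqs)
  calls <- matrix("N", nrow = nrow(f), ncol = ncol(f), dimnames = dimnames(f))
  calls[!is.na(f) & f >= threshold] <- "ALT"
  calls[!is.na(f) & f <= 1 - threshold] <- "REF"
  .codedAlleles(calls, SummarizedExperiment::rowRanges(freqs))
}
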