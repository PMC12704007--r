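# Per-SNP four-taxon topology votes from polarized coded alleles and their
# aggregation into normalized sliding-window scores.

#' Per-SNP four-taxon topology votes
#'
#' For populations X, Y, Z and an outgroup, each SNP's coded alleles are
#' polarized by the outgroup (the outgroup allele is taken as ancestral).
#' If exactly two of X, Y, Z carry the derived allele, the SNP votes for the
#' topology grouping those two: 1 = ((X,Y),Z), 2 = ((X,Z),Y), 3 = ((Y,Z),X).
#' SNPs with any ambiguous (`N`) taxon, or with 0, 1 or 3 derived taxa, are
#' uninformative (`NA`).  Topology 1 is conventionally the relationship
#' expected from the genome-wide tree.
#'
#' @param coded a [CodedAlleles-class].
#' @param quartet character of length 4: X, Y, Z, outgroup (distinct
#'   populations present in `coded`).
#' @return integer vector (one per SNP) in `{1, 2, 3}` or `NA`.
#' @examples
#' fm <- frequencyMatrix(cbind(X = 1, Y = 1, Z = 0, O = 0),
#'                       chromosome = "chr1", position = 1L)
#' snpVote(codeAlleles(fm), c("X", "Y", "Z", "O"))  # 1
#' @export
snpVote <- function(coded, quartet) {
  stopifnot(length(quartet) == 4L, !anyDuplicated(quartet))
  cl <- codedCalls(coded)
  if (!all(quartet %in% colnames(cl)))
    stop("quartet populations absent from the coded matrix")
  x <- cl[, quartet[1]]; y <- cl[, quartet[2]]
  z <- cl[, quartet[3]]; o <- cl[, quartet[4]]
  ok <- x != "N" & y != "N" & z != "N" & o != "N"
  dx <- x != o; dy <- y != o; dz <- z != o
  nd <- dx + dy + dz
  vote <- rep(NA_integer_, nrow(cl))
  vote[ok & nd == 2L & !dz] <- 1L   # X,Y derived
  vote[ok & nd == 2L & !dy] <- 2L   # X,Z derived
  vote[ok & nd == 2L & !dx] <- 3L   # Y,Z derived
  vote
}

#' Normalized sliding-window topology scores
#'
#' Votes are tallied per topology in disjoint base windows (anchored at
#' position 1); each sliding window averages the per-topology counts of its
#' constituent base windows and the averaged counts are normalized to sum to
#' one.  Windows with no informative votes have missing scores.
#'
#' @param votes integer votes from [snpVote()] (NA = uninformative).
#' @param position SNP positions (1-based, sorted).
#' @param chromosome single chromosome label for the output.
#' @param chromosomeLength length in bp (default: max position).
#' @param baseWindow disjoint tally window in bp (default 10000).
#' @param slideWindow sliding (averaging) window in bp (default 50000); must
#'   be a multiple of both `baseWindow` and `step`.
#' @param step slide step in bp (default 10000); must be a multiple of
#'   `baseWindow` and divide `slideWindow`.
#' @param normalizeFirst average per-base-window normalized scores instead
#'   of counts (the count-averaging default weights base windows by their
#'   information).
#' @return a [GenomicRanges::GRanges] with metadata columns `score1`,
#'   `score2`, `score3` (summing to 1 where informative) and
#'   `nInformative`.  Coordinates are 1-based inclusive.
#' @export
windowScores <- function(votes, position, chromosome = "chr1",
                         chromosomeLength = NULL, baseWindow = 10000L,
                         slideWindow = 50000L, step = 10000L,
                         normalizeFirst = FALSE) {
  if (slideWindow %% step != 0L)
    stop("configuration error: step must divide slideWindow")
  if (slideWindow %% baseWindow != 0L || step %% baseWindow != 0L)
    stop("configuration error: baseWindow must divide step and slideWindow")
  if (is.unsorted(position)) stop("positions must be sorted")
  if (is.null(chromosomeLength))
    chromosomeLength <- if (length(position)) max(position) else baseWindow
  nBase <- max(1L, ceiling(chromosomeLength / baseWindow))
  baseIdx <- (position - 1L) %/% baseWindow + 1L
  counts <- matrix(0, nrow = nBase, ncol = 3L)
  for (t in 1:3) {
    tb <- baseIdx[!is.na(votes) & votes == t]
    if (length(tb)) counts[, t] <- tabulate(tb, nbins = nBase)
  }
  nb <- slideWindow %/% baseWindow
  stepB <- step %/% baseWindow
  startsB <- if (nBase >= nb) seq(1L, nBase - nb + 1L, by = stepB)
             else integer(0)
  score <- matrix(NA_real_, length(startsB), 3L)
  nInf <- integer(length(startsB))
  baseScores <- if (normalizeFirst) {
    s <- counts / rowSums(counts)
    s[rowSums(counts) == 0, ] <- NA
    s
  } else NULL
  for (i in seq_along(startsB)) {
    rows <- startsB[i]:(startsB[i] + nb - 1L)
    nInf[i] <- sum(counts[rows, ])
    if (nInf[i] == 0L) next
    avg <- if (normalizeFirst)
      colMeans(baseScores[rows, , drop = FALSE], na.rm = TRUE)
    else colMeans(counts[rows, , drop = FALSE])
    score[i, ] <- avg / sum(avg)
  }
  gr <- GenomicRanges::GRanges(
    seqnames = chromosome,
    ranges = IRanges::IRanges(start = (startsB - 1L) * baseWindow + 1L,
                              width = slideWindow))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    score1 = score[, 1], score2 = score[, 2], score3 = score[, 3],
    nInformative = as.integer(nInf))
  gr
}

#' Genome-wide quartet scan
#'
#' Runs [snpVote()] and [windowScores()] for each chromosome of a coded
#' allele matrix and concatenates the results.
#'
#' @param coded a [CodedAlleles-class] spanning one or more chromosomes.
#' @param quartet X, Y, Z, outgroup population identifiers.
#' @param chromosomeSizes optional named vector of chromosome lengths (bp).
#' @param ... passed to [windowScores()].
#' @return a [GenomicRanges::GRanges] of window scores across chromosomes.
#' @export
quartetScan <- function(coded, quartet, chromosomeSizes = NULL, ...) {
  votes <- snpVote(coded, quartet)
  chrom <- snpChromosomes(coded)
  pos <- snpPositions(coded)
  out <- lapply(unique(chrom), function(ch) {
    sel <- chrom == ch
    len <- if (!is.null(chromosomeSizes)) chromosomeSizes[[ch]] else NULL
    windowScores(votes[sel], pos[sel], chromosome = ch,
                 chromosomeLength = len, ...)
  })
  do.call(c, out)
}

#' Within- and among-chromosome summaries of topology scores
#'
#' Computes the per-chromosome mean score for each topology, the variance of
#' the primary-topology score across windows within each chromosome (their
#' mean is the within-chromosome variation), and the variance of the
#' chromosome-mean primary score across chromosomes (the among-chromosome
#' variation).  Variances use the population convention (divide by n);
#' missing windows are excluded.
#'
#' @param scores a `GRanges` from [quartetScan()] (needs >= 2 chromosomes).
#' @return list with `chromosomeMeans` (chromosomes x 3 matrix),
#'   `withinChromosomeVariance` (named, per chromosome),
#'   `meanWithinVariance` and `amongChromosomeVariance`.
#' @export
scoreSummaries <- function(scores) {
  chrom <- as.character(GenomicRanges::seqnames(scores))
  if (length(unique(chrom)) < 2L) stop("need >= 2 chromosomes")
  df <- as.data.frame(S4Vectors::mcols(scores))
  popVar <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(NA_real_)
    mean((x - mean(x))^2)
  }
  means <- do.call(rbind, lapply(split(df, chrom), function(d)
    colMeans(d[, c("score1", "score2", "score3")], na.rm = TRUE)))
  withinVar <- vapply(split(df$score1, chrom), popVar, numeric(1))
  list(chromosomeMeans = means,
       withinChromosomeVariance = withinVar,
       meanWithinVariance = mean(withinVar, na.rm = TRUE),
       amongChromosomeVariance = popVar(means[, "score1"]))
}

#' Correlation between chromosome size and mean topology score
#'
#' Pearson correlation (with the Fisher-z 95 percent confidence interval and
#' two-sided t-test P-value) between chromosome sizes and per-chromosome
#' mean scores, after dropping excluded chromosomes (e.g. the Z).
#'
#' @param meanScores named numeric, per-chromosome mean score.
#' @param sizes named numeric, chromosome sizes in bp.
#' @param exclude chromosomes to drop.
#' @return list with `r`, `conf.int`, `p.value`, `n`.
#' @export
scoreSizeCorrelation <- function(meanScores, sizes, exclude = character(0)) {
  keep <- setdiff(intersect(names(meanScores), names(sizes)), exclude)
  if (length(keep) < 3L) stop("need >= 3 chromosomes after exclusion")
  x <- sizes[keep]; y <- meanScores[keep]
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined: zero variance")
  ct <- cor.test(x, y)
  list(r = unname(ct$estimate), conf.int = as.numeric(ct$conf.int),
       p.value = ct$p.value, n = length(keep))
}
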