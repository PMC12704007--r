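# Plain-text interchange: sync-style counts, covariance matrices, coded
# alleles, window scores and chromosome sizes.

#' Read and write sync-style pooled allele counts
#'
#' The sync-style layout is a TSV with columns `chrom`, `pos`, then one
#' column per population holding `ref:alt` read counts.
#'
#' @param file path to a TSV file.
#' @return [readSyncCounts()] returns an [AlleleCounts-class].
#' @export
readSyncCounts <- function(file) {
  df <- read.table(file, header = TRUE, sep = "\t",
                   colClasses = "character", check.names = FALSE)
  pops <- setdiff(names(df), c("chrom", "pos"))
  splitCounts <- function(col) {
    parts <- strsplit(col, ":", fixed = TRUE)
    list(ref = as.integer(vapply(parts, `[`, character(1), 1)),
         alt = as.integer(vapply(parts, `[`, character(1), 2)))
  }
  parsed <- lapply(df[pops], splitCounts)
  alleleCounts(ref = vapply(parsed, `[[`, integer(nrow(df)), "ref"),
               alt = vapply(parsed, `[[`, integer(nrow(df)), "alt"),
               chromosome = df$chrom, position = as.integer(df$pos),
               populations = pops)
}

#' @rdname readSyncCounts
#' @param counts an [AlleleCounts-class].
#' @export
writeSyncCounts <- function(counts, file) {
  r <- refCounts(counts)
  a <- altCounts(counts)
  body <- matrix(paste0(r, ":", a), nrow = nrow(r), dimnames = dimnames(r))
  df <- data.frame(chrom = snpChromosomes(counts),
                   pos = snpPositions(counts), body, check.names = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read and write a labeled square covariance (and SE) TSV
#'
#' @param x a [CovarianceEstimate-class].
#' @param file output path; the SE matrix goes to `<file>.se` and a one-line
#'   header comment records block size and count.
#' @export
writeCovariance <- function(x, file) {
  writeLines(sprintf("# blockSize=%d nBlocks=%d", x@blockSize, x@nBlocks),
             file)
  suppressWarnings(write.table(covMatrix(x), file, sep = "\t", quote = FALSE,
                               append = TRUE, col.names = NA))
  write.table(covSE(x), paste0(file, ".se"), sep = "\t", quote = FALSE,
              col.names = NA)
  invisible(file)
}

#' @rdname writeCovariance
#' @export
readCovariance <- function(file) {
  hdr <- strsplit(sub("^# ", "", readLines(file, n = 1L)), " ")[[1]]
  meta <- setNames(as.integer(sub(".*=", "", hdr)), sub("=.*", "", hdr))
  m <- as.matrix(read.table(file, header = TRUE, sep = "\t", skip = 1L,
                            row.names = 1L, check.names = FALSE))
  seFile <- paste0(file, ".se")
  se <- if (file.exists(seFile))
    as.matrix(read.table(seFile, header = TRUE, sep = "\t", row.names = 1L,
                         check.names = FALSE))
  else matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
  new("CovarianceEstimate", matrix = m, se = se,
      blockSize = meta[["blockSize"]], nBlocks = meta[["nBlocks"]])
}

#' Read and write coded-allele matrices
#'
#' TSV with columns `chrom`, `pos`, then one `REF`/`ALT`/`N` column per
#' population.
#'
#' @param coded a [CodedAlleles-class].
#' @param file path.
#' @export
writeCodedAlleles <- function(coded, file) {
  df <- data.frame(chrom = snpChromosomes(coded), pos = snpPositions(coded),
                   codedCalls(coded), check.names = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writeCodedAlleles
#' @export
readCodedAlleles <- function(file) {
  df <- read.table(file, header = TRUE, sep = "\t",
                   colClasses = "character", check.names = FALSE)
  pops <- setdiff(names(df), c("chrom", "pos"))
  calls <- as.matrix(df[pops])
  rownames(calls) <- NULL
  .codedAlleles(calls, .snpRanges(df$chrom, as.integer(df$pos)))
}

#' Write window scores as a BED-like TSV
#'
#' Columns: chrom, start, end (1-based inclusive), score1..3, nInformative.
#'
#' @param scores a `GRanges` from [quartetScan()] or [windowScores()].
#' @param file path.
#' @export
writeWindowScores <- function(scores, file) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(scores)),
                   start = GenomicRanges::start(scores),
                   end = GenomicRanges::end(scores),
                   as.data.frame(S4Vectors::mcols(scores)))
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a chromosome-size table
#'
#' Two-column TSV (`chrom`, `size`), with or without a header line.
#'
#' @param file path.
#' @return named numeric vector of sizes in bp.
#' @export
readChromSizes <- function(file) {
  df <- read.table(file, header = FALSE, sep = "\t",
                   colClasses = c("character", "character"))
  if (is.na(suppressWarnings(as.numeric(df[1, 2])))) df <- df[-1, ]
  setNames(as.numeric(df[[2]]), df[[1]])
}
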