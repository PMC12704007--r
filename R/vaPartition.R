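# Partitioning additive genetic variance among chromosomes from per-SNP
# effect estimates and allele frequencies.

#' Ridge estimates of per-SNP effects
#'
#' Genotype columns are centered (per-allele scale, no variance scaling) and
#' the ridge solution `beta = (X'X + lambda I)^{-1} X'y` is computed via the
#' singular value decomposition.  `lambda = "auto"` minimizes generalized
#' cross-validation, `GCV(lambda) = (RSS / n) / (1 - df / n)^2` with
#' `df = sum d_k^2 / (d_k^2 + lambda)`, over a log-spaced grid scaled to the
#' spectrum.  This deterministic shrinkage estimator supplies the
#' "effects" input of [partitionVa()]; externally produced effect estimates
#' (e.g. from a sparse polygenic sampler) can be used instead.
#'
#' @param genotypes n x p matrix of 0/1/2 genotypes.
#' @param phenotype numeric length-n phenotype vector.
#' @param lambda non-negative ridge penalty, or `"auto"` (default).
#' @return list with `effects` (per-allele effects, named by SNP),
#'   `lambda`, `df` (effective degrees of freedom), `gcv` and `intercept`.
#' @export
estimateEffects <- function(genotypes, phenotype, lambda = "auto") {
  n <- nrow(genotypes)
  p <- ncol(genotypes)
  stopifnot(n >= 10L, length(phenotype) == n)
  if (sd(phenotype) == 0) stop("phenotype must not be constant")
  X <- scale(genotypes, center = TRUE, scale = FALSE)
  y <- phenotype - mean(phenotype)
  sv <- svd(X, nu = min(n, p), nv = min(n, p))
  d2 <- sv$d^2
  uty <- crossprod(sv$u, y)
  ridge <- function(lam) {
    beta <- sv$v %*% (sv$d / (d2 + lam) * uty)
    fit <- sv$u %*% (d2 / (d2 + lam) * uty)
    rss <- sum((y - fit)^2)
    df <- sum(d2 / (d2 + lam))
    list(beta = beta, rss = rss, df = df,
         gcv = (rss / n) / (1 - df / n)^2)
  }
  if (identical(lambda, "auto")) {
    grid <- mean(d2) * 10^seq(-6, 3, length.out = 46)
    gcvs <- vapply(grid, function(l) ridge(l)$gcv, numeric(1))
    lambda <- grid[which.min(gcvs)]
  } else {
    stopifnot(is.numeric(lambda), lambda >= 0)
    if (lambda == 0 && p >= n)
      stop("lambda = 0 is singular with p >= n; use lambda > 0")
  }
  sol <- ridge(lambda)
  effects <- as.vector(sol$beta)
  names(effects) <- colnames(genotypes)
  list(effects = effects, lambda = lambda, df = sol$df, gcv = sol$gcv,
       intercept = mean(phenotype))
}

#' Partition additive genetic variance among chromosomes
#'
#' From per-SNP effects and allele frequencies,
#' `Va_c = sum_{j in c} 2 p_j (1 - p_j) beta_j^2` (linkage cross-terms
#' ignored); proportions are `Va_c / sum Va`.  The optional empirical
#' variant instead computes, per chromosome, the variance across
#' individuals of the chromosome's genetic value `X_c beta_c`, which does
#' include within-chromosome linkage covariance.
#'
#' @param effects numeric per-SNP effects (per-allele scale).
#' @param freq per-SNP allele frequencies (typically from the mapping
#'   sample, `colMeans(genotypes) / 2`).
#' @param chromosome chromosome label per SNP.
#' @param sizes optional named chromosome sizes (bp) used to report the Z
#'   chromosome's genome fraction (chromosome named `"Z"`).
#' @param method `"frequency"` (the 2p(1-p)beta^2 sum, default) or
#'   `"empirical"` (requires `genotypes`).
#' @param genotypes n x p genotype matrix, only for `method = "empirical"`.
#' @return a [VaPartition-class].
#' @examples
#' partitionVa(effects = 1, freq = 0.5, chromosome = "chr1")  # Va = 0.5
#' @export
partitionVa <- function(effects, freq, chromosome, sizes = NULL,
                        method = c("frequency", "empirical"),
                        genotypes = NULL) {
  method <- match.arg(method)
  stopifnot(length(effects) == length(freq),
            length(effects) == length(chromosome))
  chroms <- unique(chromosome)
  if (method == "frequency") {
    va <- 2 * freq * (1 - freq) * effects^2
    vaC <- vapply(chroms, function(ch) sum(va[chromosome == ch]), numeric(1))
  } else {
    if (is.null(genotypes)) stop("method = 'empirical' requires genotypes")
    vaC <- vapply(chroms, function(ch) {
      sel <- chromosome == ch
      g <- genotypes[, sel, drop = FALSE] %*% effects[sel]
      mean((g - mean(g))^2)
    }, numeric(1))
  }
  names(vaC) <- chroms
  total <- sum(vaC)
  if (total <= 0) {
    warning("all effects are zero; Va proportions undefined")
    props <- rep(NA_real_, length(vaC))
  } else props <- vaC / total
  names(props) <- chroms
  zfrac <- NA_real_
  if (!is.null(sizes) && "Z" %in% names(sizes))
    zfrac <- unname(sizes[["Z"]] / sum(sizes))
  new("VaPartition", vaByChromosome = vaC, totalVa = total,
      proportions = props, zFractionOfGenome = zfrac)
}
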