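# Ground-truth-known simulation: allele frequencies under admixture graphs,
# pool-seq read counts, chromosome-structured genomes, and polygenic traits.

# --- root-frequency distribution specs -------------------------------------

#' Root allele-frequency distribution specification
#'
#' Distribution of the ancestral (root) alternate-allele frequency, given as
#' a list: `list(dist = "uniform", min =, max =)`,
#' `list(dist = "beta", shape1 =, shape2 =)` or
#' `list(dist = "point", value =)`.  A U-shaped beta (e.g.
#' `rootDist("beta", shape1 = 0.2, shape2 = 0.2)`) emulates the skewed site
#' frequency spectra under which coded-allele analyses are informative; a
#' mid-range uniform suits covariance-model checks.
#'
#' @param dist one of `"uniform"`, `"beta"`, `"point"`.
#' @param ... distribution parameters (see above).
#' @return a validated distribution spec list.
#' @export
rootDist <- function(dist = c("uniform", "beta", "point"), ...) {
  spec <- c(list(dist = match.arg(dist)), list(...))
  validateRootDist(spec)
  spec
}

validateRootDist <- function(spec) {
  if (!is.list(spec) || is.null(spec$dist))
    stop("configuration error: root frequency distribution must be a list ",
         "with a 'dist' element")
  ok <- switch(spec$dist,
    uniform = is.numeric(spec$min) && is.numeric(spec$max) &&
      spec$min >= 0 && spec$max <= 1 && spec$min < spec$max,
    beta = is.numeric(spec$shape1) && is.numeric(spec$shape2) &&
      spec$shape1 > 0 && spec$shape2 > 0,
    point = is.numeric(spec$value) && spec$value >= 0 && spec$value <= 1,
    FALSE)
  if (!isTRUE(ok))
    stop("configuration error: invalid root frequency distribution spec")
  invisible(spec)
}

drawRootFreqs <- function(spec, n) {
  validateRootDist(spec)
  switch(spec$dist,
    uniform = runif(n, spec$min, spec$max),
    beta = rbeta(n, spec$shape1, spec$shape2),
    point = rep(spec$value, n))
}

# first and second moments of the root frequency, used by the exact
# covariance propagation
rootDistMoments <- function(spec) {
  validateRootDist(spec)
  switch(spec$dist,
    uniform = {
      a <- spec$min; b <- spec$max
      list(mean = (a + b) / 2, msq = (a^2 + a * b + b^2) / 3)
    },
    beta = {
      s <- spec$shape1 + spec$shape2
      list(mean = spec$shape1 / s,
           msq = spec$shape1 * (spec$shape1 + 1) / (s * (s + 1)))
    },
    point = list(mean = spec$value, msq = spec$value^2))
}

# --- frequency simulation ---------------------------------------------------

#' Simulate population allele frequencies under an admixture graph
#'
#' Gaussian drift along branches: a child's frequency is the parent's plus
#' Gaussian noise of variance `c * p * (1 - p)` (with `p` the parent
#' frequency), truncated to `[0, 1]`.  At a migration destination, the
#' frequency entering the destination's branch is `w` times the donor-branch
#' midpoint frequency plus `1 - w` times the tree parent's, mixed before the
#' drift on that branch.
#'
#' @param graph a [PopulationGraph-class].
#' @param nSnps number of independent SNPs (>= 1).
#' @param rootFreqDist root-frequency distribution spec (see [rootDist()]).
#' @param seed optional integer seed.
#' @param chromosome,position optional SNP coordinates (defaults to a single
#'   chromosome `"chr1"` with positions `1..nSnps`).
#' @return A [FrequencyMatrix-class] of true per-population frequencies
#'   (populations = graph leaves).
#' @examples
#' g <- populationGraph(
#'   data.frame(parent = "R", child = c("A", "B", "O"),
#'              drift = c(0.1, 0.2, 0.05)), outgroup = "O")
#' f <- simulateFrequencies(g, 100, rootDist("uniform", min = .2, max = .8),
#'                          seed = 1)
#' dim(alleleFreqs(f))
#' @export
simulateFrequencies <- function(graph, nSnps, rootFreqDist, seed = NULL,
                                chromosome = NULL, position = NULL) {
  stopifnot(nSnps >= 1)
  validObject(graph)
  validateRootDist(rootFreqDist)
  if (!is.null(seed)) set.seed(seed)
  events <- graphEvents(graph)
  vals <- new.env(parent = emptyenv())
  for (ev in events) {
    if (ev$type == "root") {
      vals[[ev$id]] <- drawRootFreqs(rootFreqDist, nSnps)
    } else if (ev$type == "mix") {
      x <- numeric(nSnps)
      for (k in seq_along(ev$parts))
        x <- x + ev$weights[k] * vals[[ev$parts[k]]]
      vals[[ev$id]] <- x
    } else {
      p <- vals[[ev$from]]
      v <- ev$drift * p * (1 - p)
      vals[[ev$id]] <- pmin(pmax(p + rnorm(nSnps, 0, sqrt(v)), 0), 1)
    }
  }
  leaves <- graphLeaves(graph)
  freq <- vapply(leaves, function(l) vals[[l]], numeric(nSnps))
  if (is.null(chromosome)) chromosome <- rep("chr1", nSnps)
  if (is.null(position)) position <- seq_len(nSnps)
  frequencyMatrix(freq, chromosome, position, populations = leaves)
}

# --- pool-seq read sampling -------------------------------------------------

#' Simulate pooled sequencing read counts from true frequencies
#'
#' Two-stage sampling per SNP and population: the pool's allele count is
#' `k ~ Binomial(2 * poolSize, p)`, the site depth is `D ~ Poisson(depth)`,
#' and alternate reads are `Binomial(D, k / (2 * poolSize))`.  Sites with
#' `D = 0` are recorded as missing (0/0 counts).
#'
#' @param freqs a [FrequencyMatrix-class] of true frequencies.
#' @param poolSize diploid individuals per pool (>= 1).
#' @param depth mean reads per SNP per population (> 0).
#' @param seed optional integer seed.
#' @return An [AlleleCounts-class].
#' @export
simulatePoolseq <- function(freqs, poolSize, depth, seed = NULL) {
  stopifnot(poolSize >= 1, depth > 0)
  f <- alleleFreqs(freqs)
  if (any(is.na(f))) stop("true frequencies must not be missing")
  if (!is.null(seed)) set.seed(seed)
  n <- length(f)
  k <- rbinom(n, 2L * poolSize, as.vector(f))
  D <- rpois(n, depth)
  a <- rbinom(n, D, k / (2 * poolSize))
  alt <- matrix(a, nrow = nrow(f), dimnames = dimnames(f))
  ref <- matrix(D - a, nrow = nrow(f), dimnames = dimnames(f))
  alleleCounts(ref, alt, snpChromosomes(freqs), snpPositions(freqs),
               populations = populations(freqs))
}

# --- genome-scale simulation ------------------------------------------------

#' Construct a SimulationConfig
#'
#' @param chromosomeSizes named numeric vector of chromosome sizes (bp).
#' @param snpsPerChromosome SNPs per chromosome; a single value is recycled.
#' @param graphAssignment a single [PopulationGraph-class] used for every
#'   chromosome, or a named list mapping each chromosome to its graph (all
#'   graphs over the same leaf set).
#' @param rootFreqDist root-frequency spec (see [rootDist()]); default is a
#'   U-shaped `beta(0.2, 0.2)`, emulating the skewed site-frequency spectra
#'   of real SNP panels.
#' @param poolDepth mean reads per SNP per population (default 100).
#' @param poolSize diploid individuals per pool (default 48, the modal pool
#'   size of the study design this emulates).
#' @return a validated [SimulationConfig-class].
#' @export
simulationConfig <- function(chromosomeSizes, snpsPerChromosome,
                             graphAssignment,
                             rootFreqDist = rootDist("beta", shape1 = 0.2,
                                                     shape2 = 0.2),
                             poolDepth = 100, poolSize = 48L) {
  ch <- names(chromosomeSizes)
  if (is.null(ch)) stop("configuration error: chromosomeSizes must be named")
  if (length(snpsPerChromosome) == 1L)
    snpsPerChromosome <- setNames(rep(snpsPerChromosome, length(ch)), ch)
  if (is(graphAssignment, "PopulationGraph"))
    graphAssignment <- setNames(rep(list(graphAssignment), length(ch)), ch)
  leaves <- lapply(graphAssignment, graphLeaves)
  if (length(unique(lapply(leaves, sort))) != 1L)
    stop("configuration error: chromosome graphs have mismatched leaf sets")
  new("SimulationConfig",
      chromosomeSizes = chromosomeSizes,
      snpsPerChromosome = setNames(as.integer(snpsPerChromosome[ch]), ch),
      graphAssignment = graphAssignment[ch],
      rootFreqDist = validateRootDist(rootFreqDist),
      poolDepth = poolDepth, poolSize = as.integer(poolSize))
}

#' Simulate a chromosome-structured pool-seq dataset with known truth
#'
#' Concatenates per-chromosome frequency simulations (each chromosome under
#' its assigned [PopulationGraph-class]; e.g. a tree for the Z and a graph
#' with a migration edge for the autosomes), draws SNP positions uniformly
#' within chromosome sizes, and samples pool-seq read counts.  One integer
#' seed drives all randomness: chromosome `k` uses sub-seed `seed + k` for
#' its frequencies and `seed + nChrom + 1` seeds the read sampling.
#'
#' @param config a [SimulationConfig-class].
#' @param seed integer seed.
#' @return A list with elements `counts` ([AlleleCounts-class]), `freqs`
#'   (the true [FrequencyMatrix-class]), and `truth` (list: per-chromosome
#'   graphs, the config and seed).
#' @export
simulateGenomeDataset <- function(config, seed = 1L) {
  validObject(config)
  chroms <- names(config@chromosomeSizes)
  freqL <- vector("list", length(chroms))
  for (k in seq_along(chroms)) {
    ch <- chroms[k]
    nS <- config@snpsPerChromosome[[ch]]
    set.seed(seed + k)
    pos <- sort(sample.int(config@chromosomeSizes[[ch]], nS))
    # resample duplicates until positions are unique (strictly increasing)
    while (anyDuplicated(pos)) {
      dup <- duplicated(pos)
      pos[dup] <- sample.int(config@chromosomeSizes[[ch]], sum(dup))
      pos <- sort(pos)
    }
    freqL[[k]] <- simulateFrequencies(
      config@graphAssignment[[ch]], nS, config@rootFreqDist,
      seed = seed + k, chromosome = rep(ch, nS), position = pos)
  }
  freq <- do.call(rbind, lapply(freqL, alleleFreqs))
  chrom <- unlist(lapply(freqL, snpChromosomes))
  pos <- unlist(lapply(freqL, snpPositions))
  freqs <- frequencyMatrix(freq, chrom, pos,
                           populations = populations(freqL[[1]]))
  counts <- simulatePoolseq(freqs, config@poolSize, config@poolDepth,
                            seed = seed + length(chroms) + 1L)
  list(counts = counts, freqs = freqs,
       truth = list(graphs = config@graphAssignment, config = config,
                    seed = seed))
}

# --- polygenic trait simulation ---------------------------------------------

#' Simulate genotypes and a sparse polygenic trait
#'
#' Genotypes are 0/1/2 draws from per-SNP allele frequencies (independent
#' SNPs, Hardy-Weinberg within the sample).  A sparse set of causal SNPs
#' carries effects `beta`; the phenotype is the genetic value plus Gaussian
#' noise scaled so the expected genetic-variance fraction equals `h2`
#' (expected genetic variance `sum_j 2 p_j (1 - p_j) beta_j^2`).
#'
#' @param nIndividuals number of individuals.
#' @param snpMap data.frame with columns `chromosome` and `position` (one row
#'   per SNP); per-SNP frequencies may be supplied in a `freq` column,
#'   otherwise drawn from `Uniform(0.05, 0.95)`.
#' @param nCausal number of causal SNPs (ignored when `effects` is given).
#' @param h2 heritability, in `[0, 1]`.
#' @param seed optional integer seed.
#' @param causalIndex optional indices of causal SNPs (length `nCausal`).
#' @param effects optional full-length effect vector overriding the random
#'   sparse draw (non-zero entries define the causal set).
#' @return list with `genotypes` (n x p matrix), `phenotype`, `effects`
#'   (true per-allele effects), `freq` (per-SNP allele frequencies) and
#'   `snpMap`.
#' @export
simulateTraitData <- function(nIndividuals, snpMap, nCausal, h2, seed = NULL,
                              causalIndex = NULL, effects = NULL) {
  stopifnot(h2 >= 0, h2 <= 1)
  p <- nrow(snpMap)
  if (is.null(effects) && nCausal > p)
    stop("configuration error: more causal SNPs than SNPs")
  if (!is.null(seed)) set.seed(seed)
  freq <- if (!is.null(snpMap$freq)) snpMap$freq else runif(p, 0.05, 0.95)
  G <- matrix(rbinom(nIndividuals * p, 2L, rep(freq, each = nIndividuals)),
              nrow = nIndividuals)
  colnames(G) <- paste0(snpMap$chromosome, ":", snpMap$position)
  if (is.null(effects)) {
    effects <- numeric(p)
    if (is.null(causalIndex)) causalIndex <- sample.int(p, nCausal)
    effects[causalIndex] <- rnorm(length(causalIndex))
  }
  gv <- as.vector(G %*% effects)
  varG <- sum(2 * freq * (1 - freq) * effects^2)
  if (h2 == 1 && varG == 0)
    stop("configuration error: h2 = 1 requires at least one causal SNP")
  noiseVar <- if (h2 == 0) {
    gv <- gv * 0; effects <- effects * 0; 1
  } else varG * (1 - h2) / h2
  phen <- gv + rnorm(nIndividuals, 0, sqrt(noiseVar))
  list(genotypes = G, phenotype = phen, effects = effects, freq = freq,
       snpMap = snpMap)
}
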