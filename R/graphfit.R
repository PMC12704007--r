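# TreeMix-style fitting of population trees and admixture graphs to
# allele-frequency covariance estimates, and the per-chromosome
# tree-likeness statistic PCVE.

doubleCenter <- function(m) {
  sweep(sweep(m, 1, rowMeans(m)), 2, colMeans(m)) + mean(m)
}

#' Expected allele-frequency covariance of an admixture graph
#'
#' On the `"drift"` scale this is the path-weight formula
#' `W = U diag(c) U'`, where `U[i, b]` is the expected fraction of leaf `i`'s
#' ancestry that drifted through branch segment `b` (products of `w` /
#' `1 - w` along migration alternatives) and `c` the segment drift values.
#' On the `"frequency"` scale the exact (pre-truncation) covariance of the
#' simulated leaf frequencies is computed by propagating second moments
#' through the graph: drift multiplies expected heterozygosity by `1 - c`
#' per branch, and the root moments come from `rootFreqDist`.  This is the
#' quantity [blockCovariance()] estimates (with `centered = TRUE`).
#'
#' @param graph a [PopulationGraph-class].
#' @param scale `"drift"` (dimensionless path weights) or `"frequency"`.
#' @param centered double-center the matrix (removes the across-population
#'   mean at each SNP, matching [blockCovariance()]'s centering).
#' @param rootFreqDist root-frequency spec, required for
#'   `scale = "frequency"`.
#' @return symmetric leaves x leaves covariance matrix.
#' @examples
#' g <- populationGraph(
#'   data.frame(parent = c("R", "R", "R"), child = c("A", "B", "O"),
#'              drift = c(0.1, 0.2, 0)), outgroup = "O")
#' expectedCovariance(g)["A", "A"]  # 0.1
#' @export
expectedCovariance <- function(graph, scale = c("drift", "frequency"),
                               centered = FALSE, rootFreqDist = NULL) {
  scale <- match.arg(scale)
  validObject(graph)
  if (scale == "drift") {
    aw <- ancestryWeights(graph)
    W <- aw$U %*% (aw$drift * t(aw$U))
  } else {
    if (is.null(rootFreqDist))
      stop("rootFreqDist is required for scale = 'frequency'")
    mom <- rootDistMoments(rootFreqDist)
    events <- graphEvents(graph)
    ids <- vapply(events, `[[`, character(1), "id")
    M <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    done <- character(0)
    for (ev in events) {
      z <- ev$id
      if (ev$type == "root") {
        M[z, z] <- mom$msq
      } else if (ev$type == "mix") {
        for (y in done)
          M[z, y] <- M[y, z] <- sum(ev$weights * M[ev$parts, y])
        M[z, z] <- as.numeric(ev$weights %*% M[ev$parts, ev$parts] %*%
                                ev$weights)
      } else {
        x <- ev$from
        for (y in done) M[z, y] <- M[y, z] <- M[x, y]
        M[z, z] <- M[x, x] + ev$drift * (mom$mean - M[x, x])
      }
      done <- c(done, z)
    }
    leaves <- graphLeaves(graph)
    W <- M[leaves, leaves] - mom$mean^2
  }
  if (centered) W <- doubleCenter(W)
  (W + t(W)) / 2
}

# --- least-squares machinery ------------------------------------------------

# design matrix: column per segment, rows = vec(n x n model matrix)
.graphDesign <- function(graph, centered) {
  aw <- ancestryWeights(graph)
  U <- aw$U
  if (centered) U <- sweep(U, 2, colMeans(U))
  X <- apply(U, 2, function(u) as.vector(outer(u, u)))
  list(X = X, segments = aw$segments)
}

# non-negative LS with exactly-collinear columns merged (weight goes to the
# first column of each duplicate group; e.g. the two root-adjacent branches
# after centering)
.nnlsSolve <- function(X, y) {
  grp <- !duplicated(round(t(X), 10))
  Xu <- X[, grp, drop = FALSE]
  keep <- colSums(abs(Xu)) > 1e-12
  coef <- numeric(ncol(X))
  if (any(keep)) {
    fit <- pracma::lsqnonneg(Xu[, keep, drop = FALSE], y)
    coef[which(grp)[keep]] <- fit$x
  }
  resid <- y - X %*% coef
  list(coef = coef, ssr = sum(resid^2))
}

.fitObjective <- function(graph, yvec, centered, rowWeights) {
  d <- .graphDesign(graph, centered)
  X <- d$X
  if (!is.null(rowWeights)) {
    X <- X * rowWeights
    yvec <- yvec * rowWeights
  }
  sol <- .nnlsSolve(X, yvec)
  list(ssr = sol$ssr, coef = setNames(sol$coef, d$segments$id),
       segments = d$segments)
}

# write fitted segment drifts back onto branches (donor halves summed)
.applyDrift <- function(graph, coef, segments) {
  drift <- tapply(coef[segments$id], segments$branch, sum)
  graph@branches$drift <- as.numeric(drift[graph@branches$child])
  graph
}

#' Fit drift values and migration weights to a covariance estimate
#'
#' For a fixed topology and fixed migration-edge placements, minimizes
#' `sum_ij (West_ij - W_ij(theta))^2` over branch drift values `c >= 0`
#' (non-negative least squares) and each migration weight `w` in (0, 1)
#' (bounded one-dimensional search), alternated to convergence (objective
#' change below `tol` or `maxIter` sweeps).
#'
#' @param graph a [PopulationGraph-class] giving topology and edge
#'   placements; its drift values and weights are used only as a starting
#'   point.
#' @param cov a [CovarianceEstimate-class] (or plain symmetric matrix) over
#'   the graph's leaf set.
#' @param centered fit the double-centered model (matching the per-SNP
#'   across-population centering of [blockCovariance()]; default TRUE).
#'   With `centered = FALSE` the raw path-weight matrix is fitted, under
#'   which all parameters are identifiable on noiseless input.
#' @param seWeighted divide residuals by the block-resampling standard
#'   errors (equal-SE fits are unaffected).
#' @param tol,maxIter alternating-optimization stopping rule.
#' @return A [GraphFit-class]; `converged` is FALSE (with a warning) if the
#'   iteration cap was hit.
#' @export
fitParameters <- function(graph, cov, centered = TRUE, seWeighted = FALSE,
                          tol = 1e-10, maxIter = 500L) {
  validObject(graph)
  W <- if (is(cov, "CovarianceEstimate")) covMatrix(cov) else cov
  leaves <- graphLeaves(graph)
  if (!all(leaves %in% rownames(W)))
    stop("covariance matrix must cover the graph's leaf set")
  W <- W[leaves, leaves]
  yvec <- as.vector(W)
  rowWeights <- NULL
  if (seWeighted) {
    if (!is(cov, "CovarianceEstimate"))
      stop("seWeighted requires a CovarianceEstimate")
    se <- covSE(cov)[leaves, leaves]
    se[se <= 0 | is.na(se)] <- min(se[se > 0], na.rm = TRUE)
    rowWeights <- 1 / as.vector(se)
  }
  mg <- graph@migrations
  conv <- TRUE
  if (nrow(mg) == 0L) {
    obj <- .fitObjective(graph, yvec, centered, rowWeights)
  } else {
    ssrPrev <- Inf
    for (it in seq_len(maxIter)) {
      for (j in seq_len(nrow(mg))) {
        fj <- function(w) {
          g2 <- graph
          g2@migrations$weight[j] <- w
          .fitObjective(g2, yvec, centered, rowWeights)$ssr
        }
        opt <- optimize(fj, interval = c(1e-6, 1 - 1e-6), tol = 1e-7)
        graph@migrations$weight[j] <- opt$minimum
      }
      obj <- .fitObjective(graph, yvec, centered, rowWeights)
      if (abs(ssrPrev - obj$ssr) < tol) break
      ssrPrev <- obj$ssr
      if (it == maxIter) {
        conv <- FALSE
        warning("fitParameters: iteration cap reached; returning best found")
      }
    }
  }
  fitted <- .applyDrift(graph, obj$coef, obj$segments)
  # fitted covariance from the segment-level solution (donor halves free)
  d <- .graphDesign(fitted, centered)
  Wfit <- matrix(d$X %*% obj$coef[d$segments$id], nrow(W),
                 dimnames = dimnames(W))
  fit <- new("GraphFit", graph = fitted, fittedCov = (Wfit + t(Wfit)) / 2,
             pcve = 0, nEdges = nrow(mg), objective = obj$ssr,
             restartLog = obj$ssr, converged = conv, seed = NA_integer_)
  fit@pcve <- pcve(fit, W)
  fit
}

#' Starting tree from a covariance matrix
#'
#' Neighbor joining on the drift distance `d_ij = W_ii + W_jj - 2 W_ij`
#' (invariant to the across-population centering of the estimate), rooted on
#' the outgroup edge, with branch drift values then initialized by
#' non-negative least squares.
#'
#' @param cov a [CovarianceEstimate-class] or symmetric matrix.
#' @param outgroup population used to root the tree.
#' @param centered passed to [fitParameters()] for the drift initialization.
#' @return a [PopulationGraph-class] with zero migration edges.
#' @export
treeFromCovariance <- function(cov, outgroup, centered = TRUE) {
  W <- if (is(cov, "CovarianceEstimate")) covMatrix(cov) else cov
  if (!(outgroup %in% rownames(W)))
    stop("input error: outgroup absent from the covariance matrix")
  d <- outer(diag(W), diag(W), "+") - 2 * W
  d <- pmax(d, 0)
  dimnames(d) <- dimnames(W)
  phy <- ape::nj(d)
  graph <- phyloToGraph(rootOnOutgroup(phy, outgroup), outgroup)
  fitParameters(graph, cov, centered = centered)@graph
}

# candidate (donor branch, destination node) placements, lexicographic
.edgeCandidates <- function(graph) {
  ids <- sort(graph@branches$child)
  existing <- paste(graph@migrations$from, graph@migrations$to)
  out <- list()
  for (from in ids) for (to in ids) {
    if (from == to || to == graph@outgroup) next
    if (paste(from, to) %in% existing) next
    out[[length(out) + 1L]] <- c(from = from, to = to)
  }
  out
}

#' Greedy admixture-graph search over 0..maxEdges migration edges
#'
#' Fits graphs with `m = 0, ..., maxEdges` migration edges.  The `m = 0`
#' topology comes from [treeFromCovariance()]; each restart perturbs it by
#' `k ~ 1 + Poisson(1)` random NNI moves and keeps the best objective (the
#' unperturbed start is always evaluated).  For `m >= 1` the best
#' `(m-1)`-edge graph seeds the search and every valid (donor branch,
#' destination node) placement is evaluated, in deterministic lexicographic
#' order; since a weight near 0 recovers the previous graph, PCVE is
#' non-decreasing in `m`.
#'
#' @param cov a [CovarianceEstimate-class].
#' @param outgroup population used for rooting.
#' @param maxEdges maximum number of migration edges (default 8).
#' @param restarts NNI-perturbed restarts for the tree search (default 20).
#' @param seed integer seed for the restart perturbations.
#' @param centered,seWeighted passed to [fitParameters()].
#' @return list of [GraphFit-class], element `m + 1` holding the `m`-edge
#'   fit.
#' @export
fitAdmixtureGraphs <- function(cov, outgroup, maxEdges = 8L, restarts = 20L,
                               seed = 1L, centered = TRUE,
                               seWeighted = FALSE) {
  stopifnot(maxEdges >= 0, restarts >= 1)
  set.seed(seed)
  base <- treeFromCovariance(cov, outgroup, centered = centered)
  starts <- c(list(base), lapply(seq_len(restarts - 1L), function(r)
    perturbTopology(base, 1L + rpois(1L, 1))))
  fits <- lapply(starts, function(g)
    tryCatch(fitParameters(g, cov, centered = centered,
                           seWeighted = seWeighted),
             error = function(e) NULL))
  fits <- fits[!vapply(fits, is.null, logical(1))]
  log0 <- vapply(fits, function(f) f@objective, numeric(1))
  best <- fits[[which.min(log0)]]
  best@restartLog <- log0
  best@seed <- as.integer(seed)
  results <- list(best)
  for (m in seq_len(maxEdges)) {
    prev <- results[[m]]@graph
    cand <- .edgeCandidates(prev)
    bestFit <- NULL
    log <- numeric(0)
    for (ce in cand) {
      g2 <- prev
      g2@migrations <- rbind(g2@migrations,
                             data.frame(from = ce[["from"]], to = ce[["to"]],
                                        weight = 0.3))
      fit <- tryCatch(
        suppressWarnings(fitParameters(g2, cov, centered = centered,
                                       seWeighted = seWeighted,
                                       maxIter = 50L)),
        error = function(e) NULL)
      if (is.null(fit)) next
      log <- c(log, fit@objective)
      if (is.null(bestFit) || fit@objective < bestFit@objective)
        bestFit <- fit
    }
    if (is.null(bestFit)) break
    bestFit@restartLog <- log
    bestFit@seed <- as.integer(seed)
    results[[m + 1L]] <- bestFit
  }
  results
}

#' Proportion of covariance explained (PCVE)
#'
#' `1 - sum_ij (West_ij - W_ij)^2 / sum_ij (West_ij - mean(West))^2`, summed
#' over all unique entries (upper triangle including the diagonal) and
#' clipped to `[0, 1]`.  A higher PCVE with fewer migration edges indicates
#' a more tree-like history.
#'
#' @param fit a [GraphFit-class].
#' @param cov a [CovarianceEstimate-class] or symmetric matrix (the estimate
#'   the fit targeted).
#' @param offDiagonalOnly exclude the diagonal from both sums.
#' @return proportion in `[0, 1]`; `NA` (with a warning) when the estimate
#'   is constant.
#' @export
pcve <- function(fit, cov, offDiagonalOnly = FALSE) {
  What <- if (is(cov, "CovarianceEstimate")) covMatrix(cov) else cov
  leaves <- rownames(fit@fittedCov)
  What <- What[leaves, leaves]
  keep <- upper.tri(What, diag = !offDiagonalOnly)
  obs <- What[keep]
  mod <- fit@fittedCov[keep]
  denom <- sum((obs - mean(obs))^2)
  if (denom <= 0) {
    warning("pcve undefined: constant covariance estimate")
    return(NA_real_)
  }
  min(max(1 - sum((obs - mod)^2) / denom, 0), 1)
}
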