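# Admixture-graph construction and the path algebra shared by the simulator
# and the covariance model.

#' Construct a PopulationGraph
#'
#' @param branches data.frame with columns `parent`, `child`, `drift`.
#'   Branches are identified by their child node; leaves are children that are
#'   never parents.
#' @param outgroup leaf identifier used for rooting and polarization.
#' @param migrations optional data.frame with columns `from` (child id of the
#'   donor branch; the edge attaches at that branch's midpoint), `to`
#'   (destination node) and `weight` in (0, 1).
#'
#' @return A validated [PopulationGraph-class].
#'
#' @examples
#' g <- populationGraph(
#'   data.frame(parent = c("R", "R", "A", "A"),
#'              child  = c("O", "A", "X", "Y"),
#'              drift  = c(0.05, 0.02, 0.1, 0.1)),
#'   outgroup = "O")
#' graphLeaves(g)
#' @export
populationGraph <- function(branches, outgroup, migrations = NULL) {
  branches$parent <- as.character(branches$parent)
  branches$child <- as.character(branches$child)
  branches$drift <- as.numeric(branches$drift)
  if (is.null(migrations))
    migrations <- data.frame(from = character(0), to = character(0),
                             weight = numeric(0))
  migrations$from <- as.character(migrations$from)
  migrations$to <- as.character(migrations$to)
  migrations$weight <- as.numeric(migrations$weight)
  root <- setdiff(branches$parent, branches$child)
  new("PopulationGraph", branches = branches, migrations = migrations,
      root = if (length(root) == 1L) root else character(0),
      outgroup = as.character(outgroup))
}

#' Leaves (population labels) of a PopulationGraph
#' @param graph a [PopulationGraph-class].
#' @return character vector of leaf identifiers.
#' @export
graphLeaves <- function(graph) {
  sort(setdiff(graph@branches$child, graph@branches$parent))
}

#' Migration edges of a PopulationGraph
#' @param graph a [PopulationGraph-class].
#' @return data.frame with columns `from`, `to`, `weight`.
#' @export
migrationEdges <- function(graph) graph@migrations

# --- internal: segments -----------------------------------------------------
# A branch that donates a migration edge is split at its midpoint into an
# upper and lower segment of drift c/2 each; other branches are one segment.
# Segment ids: "<child>" (whole / lower) and "mid:<child>" (upper).
graphSegments <- function(graph) {
  br <- graph@branches
  donors <- unique(graph@migrations$from)
  seg <- list()
  for (i in seq_len(nrow(br))) {
    ch <- br$child[i]
    if (ch %in% donors) {
      seg[[length(seg) + 1L]] <- data.frame(
        id = c(paste0("mid:", ch), ch), branch = ch,
        drift = br$drift[i] / 2, part = c("upper", "lower"))
    } else {
      seg[[length(seg) + 1L]] <- data.frame(
        id = ch, branch = ch, drift = br$drift[i], part = "whole")
    }
  }
  do.call(rbind, seg)
}

# --- internal: event schedule ----------------------------------------------
# Orders the computation of node / midpoint frequencies so that every value
# is available before it is used.  Each event is one of:
#   list(type = "root", id = root)
#   list(type = "drift", id, from, drift, segment)
#   list(type = "mix", id, parts = character ids, weights)
# Used by both the simulator and the exact moment propagation; a graph whose
# migration structure admits no such order is cyclic, which is an error.
graphEvents <- function(graph) {
  br <- graph@branches
  mg <- graph@migrations
  donors <- unique(mg$from)
  events <- list(list(type = "root", id = graph@root))
  done <- graph@root
  pending <- br$child
  midId <- function(ch) paste0("mid:", ch)
  repeat {
    if (!length(pending)) break
    progressed <- FALSE
    for (ch in pending) {
      i <- match(ch, br$child)
      par <- br$parent[i]
      if (!(par %in% done)) next
      rows <- which(mg$to == ch)
      needMid <- midId(mg$from[rows])
      if (length(rows) && !all(needMid %in% done)) next
      # top-of-branch value: tree parent, or mixture with donor midpoints
      top <- par
      if (length(rows)) {
        w <- mg$weight[rows]
        top <- paste0("top:", ch)
        events[[length(events) + 1L]] <- list(
          type = "mix", id = top,
          parts = c(needMid, par), weights = c(w, 1 - sum(w)))
        done <- c(done, top)
      }
      if (ch %in% donors) {
        events[[length(events) + 1L]] <- list(
          type = "drift", id = midId(ch), from = top,
          drift = br$drift[i] / 2, segment = midId(ch))
        events[[length(events) + 1L]] <- list(
          type = "drift", id = ch, from = midId(ch),
          drift = br$drift[i] / 2, segment = ch)
        done <- c(done, midId(ch), ch)
      } else {
        events[[length(events) + 1L]] <- list(
          type = "drift", id = ch, from = top, drift = br$drift[i],
          segment = ch)
        done <- c(done, ch)
      }
      pending <- setdiff(pending, ch)
      progressed <- TRUE
    }
    if (!progressed)
      stop("cyclic migration structure: no valid event order exists")
  }
  events
}

# --- internal: ancestry weights --------------------------------------------
# leaves x segments matrix U: U[i, b] is the expected fraction of leaf i's
# ancestry that drifted through segment b.  A lineage at a node first
# traverses its incoming branch's segments, then at the top of that branch
# follows each migration edge into the node with probability w (continuing
# upward from the donor midpoint) and the tree parent with the residual.
ancestryWeights <- function(graph) {
  seg <- graphSegments(graph)
  br <- graph@branches
  mg <- graph@migrations
  leaves <- graphLeaves(graph)
  segIds <- seg$id
  memo <- new.env(parent = emptyenv())
  upFromNode <- function(node, active = character(0)) {
    if (node == graph@root) return(setNames(numeric(length(segIds)), segIds))
    if (node %in% active) stop("cyclic migration structure")
    key <- paste0("n:", node)
    if (!is.null(memo[[key]])) return(memo[[key]])
    active <- c(active, node)
    i <- match(node, br$child)
    u <- setNames(numeric(length(segIds)), segIds)
    own <- seg$id[seg$branch == node]
    u[own] <- 1
    rows <- which(mg$to == node)
    resid <- 1 - sum(mg$weight[rows])
    u <- u + resid * upFromNode(br$parent[i], active)
    for (r in rows) {
      don <- mg$from[r]
      uu <- setNames(numeric(length(segIds)), segIds)
      uu[paste0("mid:", don)] <- 1
      dpar <- br$parent[match(don, br$child)]
      uu <- uu + upFromNode(dpar, active)
      u <- u + mg$weight[r] * uu
    }
    memo[[key]] <- u
    u
  }
  U <- t(vapply(leaves, upFromNode, numeric(nrow(seg))))
  rownames(U) <- leaves
  colnames(U) <- segIds
  list(U = U, drift = setNames(seg$drift, seg$id), segments = seg)
}

# --- phylo conversion -------------------------------------------------------

#' Convert the tree backbone of a PopulationGraph to an ape phylo
#' @param graph a [PopulationGraph-class]; migration edges are dropped.
#' @return a rooted `phylo` with drift values as branch lengths.
#' @export
graphToPhylo <- function(graph) {
  br <- graph@branches
  newick <- function(node) {
    kids <- br$child[br$parent == node]
    if (!length(kids)) return(node)
    lens <- br$drift[match(kids, br$child)]
    paste0("(", paste0(vapply(kids, newick, character(1)), ":", lens,
                       collapse = ","), ")")
  }
  ape::read.tree(text = paste0(newick(graph@root), ";"))
}

#' Build a PopulationGraph topology from a rooted phylo
#' @param phy a rooted `phylo`; internal nodes are relabeled `n1`, `n2`, ...
#' @param outgroup leaf used as the outgroup.
#' @param drift optional single drift value for every branch (default 0;
#'   drift is normally re-estimated by [fitParameters()]).
#' @return a [PopulationGraph-class] with no migration edges.
#' @export
phyloToGraph <- function(phy, outgroup, drift = 0) {
  ntip <- length(phy$tip.label)
  lab <- c(phy$tip.label, paste0("n", seq_len(phy$Nnode)))
  branches <- data.frame(parent = lab[phy$edge[, 1]],
                         child = lab[phy$edge[, 2]],
                         drift = if (is.null(phy$edge.length)) drift
                                 else pmax(phy$edge.length, 0))
  populationGraph(branches, outgroup = outgroup)
}

# internal: root a (possibly unrooted) phylo on the outgroup edge
rootOnOutgroup <- function(phy, outgroup) {
  phy <- ape::unroot(phy)
  ape::root(phy, outgroup = outgroup, resolve.root = TRUE)
}

# internal: perturb a graph topology by k random NNI moves (leaf set kept)
perturbTopology <- function(graph, k) {
  if (k <= 0) return(graph)
  phy <- graphToPhylo(graph)
  phy <- ape::unroot(phy)
  phy <- phangorn::rNNI(phy, moves = k)
  phyloToGraph(rootOnOutgroup(phy, graph@outgroup), graph@outgroup)
}

#' Extended-Newick style text for a fitted graph
#'
#' Writes the tree backbone as Newick with drift branch lengths, followed by
#' one annotation line per migration edge (`# migration: mid(<from>) ->
#' <to> [&w=..]`).
#'
#' @param graph a [PopulationGraph-class].
#' @return character vector of lines.
#' @export
graphToNewick <- function(graph) {
  phy <- graphToPhylo(graph)
  lines <- ape::write.tree(phy)
  mg <- graph@migrations
  if (nrow(mg))
    lines <- c(lines, sprintf("# migration: mid(%s) -> %s [&w=%.4f]",
                              mg$from, mg$to, mg$weight))
  lines
}

#' @describeIn populationGraph display method
#' @param object a [PopulationGraph-class].
#' @export
setMethod("show", "PopulationGraph", function(object) {
  cat(sprintf("PopulationGraph: %d leaves, %d branches, %d migration edge(s)\n",
              length(graphLeaves(object)), nrow(object@branches),
              nrow(object@migrations)))
  cat("  outgroup:", object@outgroup, "\n")
  cat(" ", graphToNewick(object)[1], "\n")
  mg <- object@migrations
  if (nrow(mg))
    for (i in seq_len(nrow(mg)))
      cat(sprintf("  migration mid(%s) -> %s, w = %.3f\n",
                  mg$from[i], mg$to[i], mg$weight[i]))
})
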