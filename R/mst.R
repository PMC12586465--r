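#' @describeIn maxSpanningTree Kruskal's algorithm on descending weights.
#'
#' Edges are sorted by decreasing weight with ties broken deterministically
#' by lexicographic (row, column) index; tie occurrences are counted on the
#' returned tree (continuous weights make ties measure-zero, but a high tie
#' rate would make edge-overlap comparisons fragile). Zero weights are kept
#' as valid (weakest) edges so the tree always exists on a complete matrix.
#' @export
setMethod("maxSpanningTree", "ConnectivityMatrix", function(x, ...) {
  kruskalMaxTree(x@weights, measure = x@measure, band = x@band)
})

#' @describeIn maxSpanningTree method for a plain symmetric weight matrix
#'   (dimnames used as channel labels).
#' @export
setMethod("maxSpanningTree", "matrix", function(x, ...) {
  if (is.null(rownames(x)))
    dimnames(x) <- list(sprintf("ch%02d", seq_len(nrow(x))),
                        sprintf("ch%02d", seq_len(nrow(x))))
  kruskalMaxTree(x, measure = "custom", band = NULL)
})

kruskalMaxTree <- function(w, measure, band) {
  n <- nrow(w)
  if (n < 2L) stop("need at least 2 nodes")
  ut <- which(upper.tri(w), arr.ind = TRUE)
  wt <- w[ut]
  if (any(!is.finite(wt))) stop("weights must be finite")
  if (any(wt < 0)) stop("weights must be non-negative")
  ord <- order(-wt, ut[, 1L], ut[, 2L])
  nTies <- sum(duplicated(wt))
  parent <- seq_len(n)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  sel <- integer(0)
  for (k in ord) {
    ra <- find(ut[k, 1L]); rb <- find(ut[k, 2L])
    if (ra != rb) {
      parent[ra] <- rb
      sel <- c(sel, k)
      if (length(sel) == n - 1L) break
    }
  }
  if (length(sel) != n - 1L)
    stop("matrix does not define a connected graph")
  labels <- rownames(w)
  edges <- data.frame(from = labels[ut[sel, 1L]], to = labels[ut[sel, 2L]],
                      weight = wt[sel], stringsAsFactors = FALSE)
  new("SpanningTree", nodes = labels, edges = edges, measure = measure,
      band = band, nTies = as.integer(nTies))
}

#' Topological metrics of a spanning tree
#'
#' Computes the six macroscale tree descriptors from the unweighted tree
#' topology (hop counts): normalized maximum degree, leaf fraction, diameter,
#' maximum betweenness centrality, mean eccentricity and tree hierarchy.
#' With \code{m = N - 1} edges and \code{L} leaf nodes:
#' \itemize{
#'   \item \code{kmax}: highest node degree divided by \code{m} (the
#'     \code{N}-normalized variant is also returned as \code{kmax_n});
#'   \item \code{leaf_fraction}: \code{L / (N - 1)}; a leaf has exactly one
#'     edge;
#'   \item \code{diameter}: longest shortest path in edges, divided by
#'     \code{m} (raw hop count in \code{diameter_edges});
#'   \item \code{bc_max}: maximum betweenness centrality, the fraction of
#'     shortest paths between other node pairs passing through a node; a
#'     leaf has BC 0, the centre of a star has BC 1;
#'   \item \code{eccentricity}: mean over nodes of the longest shortest path
#'     from that node, divided by \code{m} (raw in
#'     \code{eccentricity_edges});
#'   \item \code{tree_hierarchy}: \code{Th = L / (2 m BCmax)}.
#' }
#' Diameter and eccentricity are normalized by \code{m} so that all metrics
#' share the [0, 1] scale; the unnormalized values are always emitted
#' alongside. For \code{N < 3} betweenness and tree hierarchy are undefined
#' and returned as \code{NA}.
#'
#' @param tree a [SpanningTree-class].
#' @return named list of metrics, including \code{n_nodes}, \code{n_edges}
#'   and \code{n_leaves}, and the per-node vectors \code{degree} and
#'   \code{betweenness}.
#' @export
mstMetrics <- function(tree) {
  stopifnot(is(tree, "SpanningTree"))
  n <- length(tree@nodes)
  m <- n - 1L
  g <- igraph::graph_from_data_frame(tree@edges[, c("from", "to")],
                                     directed = FALSE, vertices = tree@nodes)
  deg <- igraph::degree(g)
  L <- sum(deg == 1L)
  dmat <- igraph::distances(g)          # unweighted hop counts
  ecc <- apply(dmat, 1L, max)
  diam <- max(ecc)
  if (n >= 3L) {
    bc <- igraph::betweenness(g, directed = FALSE, normalized = TRUE)
    bcMax <- max(bc)
    th <- L / (2 * m * bcMax)
  } else {
    bc <- rep(NA_real_, n)
    bcMax <- NA_real_
    th <- NA_real_
  }
  list(kmax = max(deg) / m, kmax_n = max(deg) / n,
       leaf_fraction = L / (n - 1L),
       diameter = diam / m, diameter_edges = diam,
       bc_max = bcMax,
       eccentricity = mean(ecc) / m, eccentricity_edges = mean(ecc),
       tree_hierarchy = th,
       n_nodes = n, n_edges = m, n_leaves = L,
       degree = deg, betweenness = bc)
}

#' Mean connectivity over the tree edges
#'
#' The spanning-tree alternative to the whole-brain average: the mean of the
#' connectivity weights restricted to the N - 1 tree edges (the PLI_MST /
#' AECc_MST summary). Because the maximum tree picks the strongest edges,
#' this is always at least the whole-brain mean.
#'
#' @param tree a [SpanningTree-class].
#' @param matrix the [ConnectivityMatrix-class] (or plain matrix) the tree
#'   was derived from; node sets must match.
#' @return scalar mean weight.
#' @export
mstEdgeMean <- function(tree, matrix) {
  w <- if (is(matrix, "ConnectivityMatrix")) matrix@weights else matrix
  if (!setequal(tree@nodes, rownames(w)) ||
      length(tree@nodes) != nrow(w))
    stop("tree and matrix node sets differ")
  mean(w[cbind(tree@edges$from, tree@edges$to)])
}

#' Edge overlap between two spanning trees
#'
#' Percentage of edges (as unordered channel pairs) shared between two trees
#' over the same node set: \code{100 |A intersect B| / (N - 1)}. A
#' topological reliability index: 100 means identical backbones, 0 means
#' edge-disjoint trees.
#'
#' @param treeA,treeB [SpanningTree-class] objects on identical node sets.
#' @return overlap percentage in [0, 100].
#' @export
mstOverlap <- function(treeA, treeB) {
  if (!setequal(treeA@nodes, treeB@nodes))
    stop("trees are defined on different node sets")
  a <- edgeKeys(treeA)
  b <- edgeKeys(treeB)
  100 * length(intersect(a, b)) / (length(treeA@nodes) - 1L)
}

edgeKeys <- function(tree) {
  lo <- pmin(tree@edges$from, tree@edges$to)
  hi <- pmax(tree@edges$from, tree@edges$to)
  paste(lo, hi, sep = "\r")
}

#' Convert an overlap percentage to an edge count
#'
#' A tree on \code{nNodes} channels has \code{nNodes - 1} edges, so a mean
#' overlap of p percent corresponds to \code{p / 100 * (nNodes - 1)} shared
#' edges (e.g. 10.8 percent on 64 channels is 6.8 edges).
#'
#' @param percent overlap percentage in [0, 100].
#' @param nNodes number of channels.
#' @return equivalent number of shared edges.
#' @export
overlapEdgeCount <- function(percent, nNodes) {
  stopifnot(all(percent >= 0 & percent <= 100), nNodes >= 2)
  percent / 100 * (nNodes - 1)
}
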