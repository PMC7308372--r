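#' Build a hard-threshold co-expression network
#'
#' Computes all pairwise expression correlations among the candidate
#' transcripts (same machinery and defaults as
#' \code{\link{correlateTrait}}: log2(x + 1), Pearson, two-tailed t-based p)
#' and keeps an edge wherever p <= \code{pCutoff}. In tissue mode, set
#' \code{minExpressed = 2} to drop transcripts expressed (> 0) in fewer
#' than two samples before correlating, as a correlation coefficient is not
#' meaningful for them. An r-magnitude threshold is available as an
#' alternative edge rule but is off by default: the p-value rule is primary.
#'
#' @param x \linkS4class{TraitExperiment} or abundance matrix.
#' @param candidates transcript IDs to build over (default: all rows).
#' @param pCutoff two-tailed p-value threshold for an edge.
#' @param method,logTransform correlation settings, as in
#'   \code{\link{correlateTrait}}.
#' @param minExpressed minimum number of samples with value > 0 a
#'   transcript needs to enter the network (0 disables; use 2 in tissue mode).
#' @param rCutoff optional absolute-correlation threshold; when non-NULL it
#'   replaces the p rule (edge iff |r| >= rCutoff).
#' @return a \linkS4class{CoexpressionNetwork}.
#' @export
buildNetwork <- function(x, candidates = NULL, pCutoff = 0.05,
                         method = "pearson", logTransform = TRUE,
                         minExpressed = 0L, rCutoff = NULL) {
  if (is(x, "TraitExperiment")) x <- abundance(x)
  if (is.null(candidates)) candidates <- rownames(x)
  missing <- setdiff(candidates, rownames(x))
  if (length(missing))
    stop("candidates absent from expression matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  m <- x[candidates, , drop = FALSE]
  if (minExpressed > 0L)
    m <- m[rowSums(m > 0) >= minExpressed, , drop = FALSE]
  kept <- rownames(m)
  if (length(kept) < 2L || ncol(m) < 4L)
    stop("need >= 2 candidate transcripts and >= 4 samples")
  if (logTransform) m <- log2(m + 1)
  cp <- .corPairs(m, method)
  if (all(is.na(cp$r[upper.tri(cp$r)])))
    warning("all candidate transcripts are constant; network has no edges")
  ut <- which(upper.tri(cp$p), arr.ind = TRUE)
  keep <- if (is.null(rCutoff)) {
    !is.na(cp$p[ut]) & cp$p[ut] <= pCutoff
  } else {
    !is.na(cp$r[ut]) & abs(cp$r[ut]) >= rCutoff
  }
  ut <- ut[keep, , drop = FALSE]
  a <- kept[ut[, 1L]]; b <- kept[ut[, 2L]]
  swap <- a > b
  edges <- data.frame(node_a = ifelse(swap, b, a),
                      node_b = ifelse(swap, a, b),
                      r = cp$r[ut], p = cp$p[ut],
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$node_a, edges$node_b), , drop = FALSE]
  rownames(edges) <- NULL
  new("CoexpressionNetwork", candidates = kept, edges = edges,
      cutoff = if (is.null(rCutoff)) pCutoff else 1, nSamples = ncol(m))
}

#' Convert a co-expression network to an igraph object
#'
#' @param network a \linkS4class{CoexpressionNetwork}.
#' @param isolated include isolated candidate transcripts as vertices.
#' @return an undirected \pkg{igraph} graph; edges carry r, p and
#'   weight = |r|.
#' @export
asIgraph <- function(network, isolated = FALSE) {
  e <- network@edges
  verts <- if (isolated) network@candidates else networkNodes(network)
  g <- igraph::graph_from_data_frame(
    e[, c("node_a", "node_b", "r", "p")], directed = FALSE,
    vertices = data.frame(name = verts))
  igraph::E(g)$weight <- abs(igraph::E(g)$r)
  g
}

#' Markov clustering of a co-expression network
#'
#' Deterministic MCL on the |r|-weighted adjacency with unit self-loops:
#' column-normalize, then alternate expansion (matrix power
#' \code{expansion}) and inflation (elementwise power \code{inflation} with
#' renormalization) until the matrix change falls below \code{tol}.
#' Clusters are the connected components of the converged attractor
#' structure; nodes of different connected components are never merged.
#' The correlation sign is ignored (weights are |r|).
#'
#' @param network \linkS4class{CoexpressionNetwork} (or igraph graph with a
#'   weight attribute).
#' @param inflation inflation exponent (default 2.2).
#' @param expansion expansion power (default 2).
#' @param tol convergence tolerance on the max entry change.
#' @param maxIter iteration cap.
#' @return named integer vector: cluster ID per (non-isolated) node,
#'   numbered by decreasing cluster size.
#' @export
markovClusters <- function(network, inflation = 2.2, expansion = 2L,
                           tol = 1e-6, maxIter = 100L) {
  g <- if (is(network, "CoexpressionNetwork")) asIgraph(network) else network
  n <- igraph::vcount(g)
  if (n == 0L) return(stats::setNames(integer(), character()))
  A <- as.matrix(igraph::as_adjacency_matrix(g, attr = "weight",
                                             sparse = TRUE))
  diag(A) <- 1
  M <- sweep(A, 2L, colSums(A), "/")
  for (i in seq_len(maxIter)) {
    Mexp <- M
    for (e in seq_len(expansion - 1L)) Mexp <- Mexp %*% M
    Minf <- Mexp^inflation
    Minf <- sweep(Minf, 2L, colSums(Minf), "/")
    Minf[Minf < 1e-12] <- 0
    Minf <- sweep(Minf, 2L, colSums(Minf), "/")
    if (max(abs(Minf - M)) < tol) { M <- Minf; break }
    M <- Minf
  }
  B <- (M > 1e-6) | t(M > 1e-6)
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(B, mode = "undirected"))$membership
  names(comp) <- igraph::V(g)$name
  sizes <- table(comp)
  relabel <- stats::setNames(seq_along(sizes),
                             names(sort(sizes, decreasing = TRUE)))
  stats::setNames(as.integer(relabel[as.character(comp)]), names(comp))
}

#' Vertex connectivity of a co-expression network
#'
#' The minimum number of nodes whose removal disconnects part of the
#' network -- the robustness measure used for the connectivity-fold
#' comparison. Computed on the subgraph induced by non-isolated nodes:
#' 0 when that subgraph is disconnected or has fewer than 2 nodes, and
#' n - 1 for a complete graph on n nodes.
#'
#' @param network \linkS4class{CoexpressionNetwork} or igraph graph.
#' @return integer >= 0.
#' @export
vertexConnectivity <- function(network) {
  g <- if (is(network, "CoexpressionNetwork")) asIgraph(network) else network
  if (igraph::vcount(g) < 2L) return(0L)
  as.integer(igraph::vertex_connectivity(g))
}

#' Summary counts of a co-expression network
#'
#' @param network a \linkS4class{CoexpressionNetwork}.
#' @return list(n_nodes_connected, n_edges, n_clusters, connectivity);
#'   nodes are counted by edge participation.
#' @export
networkSummary <- function(network) {
  nodes <- networkNodes(network)
  if (length(nodes) == 0L)
    return(list(n_nodes_connected = 0L, n_edges = 0L, n_clusters = 0L,
                connectivity = 0L))
  cl <- markovClusters(network)
  list(n_nodes_connected = length(nodes),
       n_edges = nrow(network@edges),
       n_clusters = length(unique(cl)),
       connectivity = vertexConnectivity(network))
}
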