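# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# chi-square survival function with df = 1 via the normal CDF:
# P(X > x) = 2 * (1 - Phi(sqrt(x)))
chisq1SfOracle <- function(x) 2 * pnorm(-sqrt(x))

# F survival function for numerator df = 2 in closed form:
# P(F > f) = (1 + 2 f / d2)^(-d2 / 2)
f2SfOracle <- function(f, d2) (1 + 2 * f / d2)^(-d2 / 2)

# exhaustive minimum vertex cut on a small undirected graph given as a
# 2-column character edge matrix over `nodes`; n - 1 when no cut exists
bruteVertexConnectivity <- function(nodes, edges) {
  n <- length(nodes)
  if (n < 2L) return(0L)
  adj <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  if (nrow(edges)) {
    adj[cbind(edges[, 1], edges[, 2])] <- TRUE
    adj[cbind(edges[, 2], edges[, 1])] <- TRUE
  }
  connected <- function(keep) {
    m <- sum(keep)
    if (m <= 1L) return(TRUE)
    idx <- which(keep)
    seen <- rep(FALSE, n)
    stack <- idx[1]; seen[idx[1]] <- TRUE
    while (length(stack)) {
      v <- stack[1]; stack <- stack[-1]
      nb <- which(adj[v, ] & keep & !seen)
      seen[nb] <- TRUE
      stack <- c(stack, nb)
    }
    all(seen[idx])
  }
  if (!connected(rep(TRUE, n))) return(0L)
  for (k in seq_len(n - 2L)) {
    subsets <- combn(n, k)
    for (j in seq_len(ncol(subsets))) {
      keep <- rep(TRUE, n)
      keep[subsets[, j]] <- FALSE
      if (!connected(keep)) return(k)
    }
  }
  n - 1L
}

# naive dense MCL, written independently of the package implementation
naiveMCL <- function(adj, inflation = 2.2, maxIter = 200L) {
  diag(adj) <- 1
  M <- apply(adj, 2, function(col) col / sum(col))
  for (it in seq_len(maxIter)) {
    M2 <- M %*% M
    M2 <- M2^inflation
    M2 <- apply(M2, 2, function(col) col / sum(col))
    M2[M2 < 1e-14] <- 0
    M2 <- apply(M2, 2, function(col) col / sum(col))
    if (max(abs(M2 - M)) < 1e-8) { M <- M2; break }
    M <- M2
  }
  n <- nrow(M)
  # union nodes sharing any attractor row support
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) {
    members <- which(M[i, ] > 1e-7)
    if (length(members) > 1L)
      for (m in members[-1]) parent[find(m)] <- find(members[1])
    if (length(members) >= 1L)
      parent[find(i)] <- find(members[1])
  }
  roots <- vapply(seq_len(n), find, 0L)
  match(roots, unique(roots))
}

# all-pairs edge recomputation with cor.test (the reference correlation
# machinery), on an already-transformed matrix
bruteEdges <- function(mat, cutoff, method = "pearson") {
  ids <- rownames(mat)
  out <- list()
  for (i in seq_len(nrow(mat) - 1L)) for (j in seq(i + 1L, nrow(mat))) {
    ct <- suppressWarnings(cor.test(mat[i, ], mat[j, ], method = method,
                                    exact = FALSE))
    if (!is.na(ct$p.value) && ct$p.value <= cutoff) {
      a <- ids[i]; b <- ids[j]
      out[[length(out) + 1L]] <- sort(c(a, b))
    }
  }
  if (!length(out)) return(character())
  sort(vapply(out, paste, "", collapse = "|"))
}

edgeKeys <- function(network) {
  e <- networkEdges(network)
  sort(paste(e$node_a, e$node_b, sep = "|"))
}

# random small graph as (nodes, edge matrix)
randomGraph <- function(n, pEdge = 0.4) {
  nodes <- paste0("v", seq_len(n))
  pairs <- combn(nodes, 2)
  keep <- runif(ncol(pairs)) < pEdge
  list(nodes = nodes,
       edges = t(pairs[, keep, drop = FALSE]))
}

# wrap an edge list into a CoexpressionNetwork (r/p filled with dummies)
networkFromEdges <- function(nodes, edges, cutoff = 0.05) {
  if (is.null(dim(edges))) edges <- matrix(edges, ncol = 2)
  a <- pmin(edges[, 1], edges[, 2]); b <- pmax(edges[, 1], edges[, 2])
  df <- unique(data.frame(node_a = a, node_b = b,
                          r = 0.9, p = cutoff / 2,
                          stringsAsFactors = FALSE))
  df <- df[order(df$node_a, df$node_b), , drop = FALSE]
  rownames(df) <- NULL
  new("CoexpressionNetwork", candidates = nodes, edges = df,
      cutoff = cutoff, nSamples = 10L)
}

emptyNetwork <- function(nodes, cutoff = 0.05) {
  new("CoexpressionNetwork", candidates = nodes,
      edges = data.frame(node_a = character(), node_b = character(),
                         r = numeric(), p = numeric(),
                         stringsAsFactors = FALSE),
      cutoff = cutoff, nSamples = 10L)
}
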