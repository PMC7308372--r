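test_that("identical profiles form a complete triangle", {
  m <- matrix(rep(c(1, 5, 2, 8, 3, 9, 4, 7), each = 3), nrow = 3,
              byrow = FALSE)
  rownames(m) <- c("a", "b", "c")
  colnames(m) <- paste0("s", 1:8)
  nw <- buildNetwork(m, pCutoff = 0.05, logTransform = FALSE)
  expect_identical(nrow(networkEdges(nw)), 3L)
  expect_setequal(networkNodes(nw), c("a", "b", "c"))
  expect_true(all(abs(networkEdges(nw)$r - 1) < 1e-12))
})

test_that("independent noise at a severe cutoff yields an empty network", {
  set.seed(14)
  m <- matrix(rnorm(10 * 50), 10,
              dimnames = list(paste0("t", 1:10), paste0("s", 1:50)))
  nw <- buildNetwork(m, pCutoff = 1e-8, logTransform = FALSE)
  expect_identical(nrow(networkEdges(nw)), 0L)
  expect_identical(length(networkNodes(nw)), 0L)
  expect_identical(length(candidateSet(nw)), 10L)
})

test_that("edge set equals brute-force all-pairs recomputation", {
  set.seed(15)
  for (rep in 1:3) {
    m <- matrix(rlnorm(6 * 30), 6,
                dimnames = list(paste0("t", 1:6), paste0("s", 1:30)))
    m[1:2, ] <- m[1:2, ] * matrix(rep(rlnorm(30, 0, 1), each = 2), 2)
    for (cutoff in c(0.05, 0.01)) {
      nw <- buildNetwork(m, pCutoff = cutoff)
      expect_identical(edgeKeys(nw), bruteEdges(log2(m + 1), cutoff))
    }
  }
})

test_that("constant candidate sets give a warned, empty edge set", {
  m <- matrix(5, 4, 10, dimnames = list(paste0("t", 1:4), paste0("s", 1:10)))
  expect_warning(nw <- buildNetwork(m, logTransform = FALSE), "constant")
  expect_identical(nrow(networkEdges(nw)), 0L)
})

test_that("tightening the cutoff never adds nodes or edges", {
  set.seed(16)
  m <- matrix(rlnorm(12 * 20), 12,
              dimnames = list(paste0("t", 1:12), paste0("s", 1:20)))
  grid <- defaultPGrid()
  nets <- lapply(grid, function(cc) buildNetwork(m, pCutoff = cc))
  edges <- vapply(nets, function(nw) nrow(networkEdges(nw)), 0L)
  nodes <- vapply(nets, function(nw) length(networkNodes(nw)), 0L)
  expect_true(all(diff(edges) <= 0))
  expect_true(all(diff(nodes) <= 0))
  # and edge sets are nested
  for (i in seq_len(length(grid) - 1))
    expect_true(all(edgeKeys(nets[[i + 1]]) %in% edgeKeys(nets[[i]])))
})

test_that("Markov clustering respects components and splits barbells", {
  tri1 <- cbind(c("a", "b", "c"), c("b", "c", "a"))
  tri2 <- cbind(c("x", "y", "z"), c("y", "z", "x"))
  nw <- networkFromEdges(c("a", "b", "c", "x", "y", "z"), rbind(tri1, tri2))
  cl <- markovClusters(nw)
  expect_identical(length(unique(cl)), 2L)
  expect_identical(length(unique(cl[c("a", "b", "c")])), 1L)
  expect_identical(length(unique(cl[c("x", "y", "z")])), 1L)

  single <- networkFromEdges(c("a", "b"), cbind("a", "b"))
  expect_identical(unname(markovClusters(single)), c(1L, 1L))

  # barbell: two K4 joined by one edge separate at inflation 2.2
  k4 <- function(v) t(combn(v, 2))
  bar <- rbind(k4(paste0("L", 1:4)), k4(paste0("R", 1:4)),
               cbind("L1", "R1"))
  nwB <- networkFromEdges(c(paste0("L", 1:4), paste0("R", 1:4)), bar)
  clB <- markovClusters(nwB, inflation = 2.2)
  expect_identical(length(unique(clB)), 2L)
  expect_identical(length(unique(clB[paste0("L", 1:4)])), 1L)
})

test_that("Markov clustering matches an independent dense implementation", {
  set.seed(17)
  for (i in 1:5) {
    g <- randomGraph(sample(5:9, 1), pEdge = 0.5)
    if (nrow(g$edges) == 0) next
    nw <- networkFromEdges(g$nodes, g$edges)
    nodes <- networkNodes(nw)
    cl <- markovClusters(nw)
    adj <- matrix(0, length(nodes), length(nodes),
                  dimnames = list(nodes, nodes))
    e <- networkEdges(nw)
    adj[cbind(e$node_a, e$node_b)] <- abs(e$r)
    adj[cbind(e$node_b, e$node_a)] <- abs(e$r)
    ref <- naiveMCL(adj)
    # same partition up to label permutation: co-membership matrices agree
    a <- unname(outer(cl[nodes], cl[nodes], "=="))
    b <- unname(outer(ref, ref, "=="))
    expect_identical(a, b)
  }
})

test_that("cluster count never falls below the component count", {
  set.seed(18)
  for (i in 1:10) {
    g <- randomGraph(7, pEdge = 0.3)
    if (nrow(g$edges) == 0) next
    nw <- networkFromEdges(g$nodes, g$edges)
    cl <- markovClusters(nw)
    comp <- igraph::components(asIgraph(nw))$membership
    expect_gte(length(unique(cl)), length(unique(comp)))
    # clusters never span components
    for (cc in unique(cl))
      expect_identical(length(unique(comp[names(cl)[cl == cc]])), 1L)
  }
})

test_that("vertex connectivity follows the graph-theory identities", {
  k4 <- networkFromEdges(paste0("v", 1:4), t(combn(paste0("v", 1:4), 2)))
  expect_identical(vertexConnectivity(k4), 3L)
  path <- networkFromEdges(c("a", "b", "c"), rbind(c("a", "b"), c("b", "c")))
  expect_identical(vertexConnectivity(path), 1L)
  disc <- networkFromEdges(c("a", "b", "c", "d"),
                           rbind(c("a", "b"), c("c", "d")))
  expect_identical(vertexConnectivity(disc), 0L)
  expect_identical(vertexConnectivity(emptyNetwork(c("a", "b"))), 0L)
})

test_that("connectivity is bounded by the minimum degree", {
  set.seed(19)
  for (i in 1:20) {
    g <- randomGraph(sample(4:8, 1), pEdge = 0.5)
    if (nrow(g$edges) == 0) next
    nw <- networkFromEdges(g$nodes, g$edges)
    kap <- vertexConnectivity(nw)
    deg <- igraph::degree(asIgraph(nw))
    expect_lte(kap, min(deg))
  }
})

test_that("network summary recounts by independent traversal", {
  tri <- networkFromEdges(c("a", "b", "c"),
                          rbind(c("a", "b"), c("b", "c"), c("a", "c")))
  expect_identical(networkSummary(tri),
                   list(n_nodes_connected = 3L, n_edges = 3L,
                        n_clusters = 1L, connectivity = 2L))
  expect_identical(networkSummary(emptyNetwork(c("a", "b"))),
                   list(n_nodes_connected = 0L, n_edges = 0L,
                        n_clusters = 0L, connectivity = 0L))

  te <- simulateDataset(simConfig(nSamples = 30, nTraitGenes = 5,
                                  nBackgroundGenes = 5, seed = 23))
  tr <- groundTruth(te)
  nw <- buildNetwork(te, candidates = tr$trait_transcripts, pCutoff = 0.05)
  s <- networkSummary(nw)
  e <- networkEdges(nw)
  expect_identical(s$n_edges, nrow(e))
  expect_identical(s$n_nodes_connected,
                   length(unique(c(e$node_a, e$node_b))))
})

test_that("tissue-mode expression filter drops near-silent transcripts", {
  m <- matrix(rlnorm(4 * 8), 4,
              dimnames = list(paste0("t", 1:4), paste0("T", 1:8)))
  m[1, ] <- 0; m[1, 3] <- 5  # expressed in a single tissue
  nw <- buildNetwork(m, pCutoff = 0.05, minExpressed = 2)
  expect_false("t1" %in% candidateSet(nw))
  expect_true(all(c("t2", "t3", "t4") %in% candidateSet(nw)))
})
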