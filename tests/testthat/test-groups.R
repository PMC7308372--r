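test_that("phenotype partition sorts, drops around the median, stays contiguous", {
  ph <- setNames(as.numeric(1:9), paste0("s", 1:9))
  part <- partitionPhenotype(ph, 3, 3)
  g <- phenotypeGroups(part)
  expect_identical(g$G1, paste0("s", 1:3))
  expect_identical(g$G2, paste0("s", 4:6))
  expect_identical(g$G3, paste0("s", 7:9))

  ph10 <- setNames(as.numeric(1:10), sprintf("s%02d", 1:10))
  part10 <- partitionPhenotype(ph10, 3, 3)
  expect_identical(length(part10@dropped), 1L)
  expect_true(part10@dropped %in% c("s05", "s06"))
  # remaining ranks contiguous within groups
  g10 <- phenotypeGroups(part10)
  ranks <- lapply(g10, function(ids) rank(ph10)[ids])
  expect_true(all(vapply(seq_len(2), function(i)
    max(ranks[[i]]) < min(ranks[[i + 1]]), TRUE)))

  set.seed(41)
  ph42 <- setNames(rnorm(42, 20, 4), sprintf("s%02d", 1:42))
  p42 <- partitionPhenotype(ph42, 3, 14)
  means <- p42@stats$mean
  expect_true(all(diff(means) > 0))
  expect_identical(unname(p42@stats$n), c(14L, 14L, 14L))
  expect_error(partitionPhenotype(ph42, 4, 14), "insufficient")

  # affine phenotype rescaling leaves the partition unchanged
  p42b <- partitionPhenotype(2.5 * ph42 + 7, 3, 14)
  expect_identical(phenotypeGroups(p42), phenotypeGroups(p42b))

  # group selection keeps the extremes and middle
  sel <- partitionPhenotype(ph42, 3, 14, selectedGroups = c(1, 3))
  expect_identical(names(phenotypeGroups(sel)), c("G1", "G3"))
})

test_that("one-way ANOVA with LSD matches hand computation and the F oracle", {
  g <- list(G1 = c(1, 2, 3), G2 = c(2, 3, 4), G3 = c(3, 4, 5))
  a <- anovaLsd(g, alpha = 0.01)
  expect_equal(a$F, 3.0, tolerance = 1e-12)
  expect_identical(c(a$df_between, a$df_within), c(2L, 6L))
  expect_equal(a$p, f2SfOracle(3, 6), tolerance = 1e-12)
  expect_equal(a$p, 0.125, tolerance = 1e-9)
  # not separated at alpha 0.01: all groups share a letter
  expect_identical(length(unique(a$letters)), 1L)

  same <- list(a = c(1, 2, 3), b = c(1, 2, 3))
  a2 <- anovaLsd(same)
  expect_identical(a2$F, 0)
  expect_identical(a2$p, 1)
  expect_identical(length(unique(a2$letters)), 1L)

  far <- list(lo = rnorm(5, 0, 0.1), mid = rnorm(5, 10, 0.1),
              hi = rnorm(5, 20, 0.1))
  a3 <- anovaLsd(far, alpha = 0.01)
  expect_identical(length(unique(a3$letters)), 3L)
  expect_identical(unname(a3$letters), c("a", "b", "c"))

  zero <- list(a = c(1, 1), b = c(2, 2))
  a4 <- anovaLsd(zero)
  expect_true(a4$exact_separation)
  expect_identical(a4$p, 0)

  # reference check against aov on a random design
  set.seed(44)
  g5 <- list(x = rnorm(8, 1), y = rnorm(8, 1.5), z = rnorm(8, 0.5))
  a5 <- anovaLsd(g5)
  fit <- summary(aov(v ~ grp, data.frame(
    v = unlist(g5), grp = rep(names(g5), each = 8))))[[1]]
  expect_equal(a5$F, fit[["F value"]][1], tolerance = 1e-10)
  expect_equal(a5$p, fit[["Pr(>F)"]][1], tolerance = 1e-10)
})

test_that("percent differences enumerate all pairs", {
  pd <- percentDifferences(c(A = 4, B = 5))
  expect_equal(pd$percent_diff, 25)
  expect_equal(percentDifferences(c(a = 3, b = 3))$percent_diff, 0)

  pd3 <- percentDifferences(c(G1 = 10, G2 = 14, G3 = 16.1))
  byHand <- c(100 * (14 - 10) / 10, 100 * (16.1 - 10) / 10,
              100 * (16.1 - 14) / 14)
  expect_equal(sort(pd3$percent_diff), sort(byHand), tolerance = 1e-12)
  expect_equal(attr(pd3, "range_min"), 15, tolerance = 1e-12)
  expect_equal(attr(pd3, "range_max"), 61, tolerance = 1e-12)
  expect_error(percentDifferences(c(1, -2)), "positive")
})

test_that("consistency is intersection over union of nodes and edges", {
  nodes <- c("a", "b", "c", "d", "e")
  tri <- rbind(c("a", "b"), c("b", "c"), c("a", "c"))
  nw <- networkFromEdges(nodes, tri)
  same <- networkConsistency(list(nw, nw, nw))
  expect_equal(same$node_consistency_pct, 100)
  expect_equal(same$edge_consistency_pct, 100)

  # node sets {a,b,c}, {b,c,d}, {b,c,e}: |I| = 2, |U| = 5
  n1 <- networkFromEdges(nodes, rbind(c("a", "b"), c("b", "c")))
  n2 <- networkFromEdges(nodes, rbind(c("b", "c"), c("c", "d")))
  n3 <- networkFromEdges(nodes, rbind(c("b", "c"), c("c", "e")))
  got <- networkConsistency(list(n1, n2, n3))
  expect_equal(got$node_consistency_pct, 40)

  # pairwise-disjoint edge sets
  d1 <- networkFromEdges(nodes, rbind(c("a", "b")))
  d2 <- networkFromEdges(nodes, rbind(c("c", "d")))
  expect_equal(networkConsistency(list(d1, d2))$edge_consistency_pct, 0)

  # empty union is defined as 100 with a flag
  e0 <- networkConsistency(list(emptyNetwork(nodes), emptyNetwork(nodes)))
  expect_equal(e0$node_consistency_pct, 100)
  expect_true(e0$empty_union)

  expect_error(networkConsistency(list(n1, networkFromEdges(c("a", "b"),
                                                            rbind(c("a", "b"))))),
               "candidate")
})

test_that("node consistency dominates edge consistency on random networks", {
  set.seed(47)
  for (i in 1:15) {
    nodes <- paste0("v", 1:8)
    nets <- lapply(1:3, function(j) {
      g <- randomGraph(8, pEdge = runif(1, 0.2, 0.6))
      if (nrow(g$edges) == 0) emptyNetwork(nodes)
      else networkFromEdges(nodes, g$edges)
    })
    cons <- networkConsistency(nets)
    expect_gte(cons$node_consistency_pct, cons$edge_consistency_pct)
  }
})

test_that("candidate-denominator convention divides by the candidate set", {
  nodes <- c("a", "b", "c", "d")
  nw <- networkFromEdges(nodes, rbind(c("a", "b"), c("b", "c")))
  got <- networkConsistency(list(nw, nw), method = "candidate")
  expect_equal(got$node_consistency_pct, 100 * 3 / 4)
  expect_equal(got$edge_consistency_pct, 100 * 2 / choose(4, 2))
})

test_that("group consistency integrates partition, ANOVA and networks", {
  te <- simulateDataset(simConfig(nSamples = 42, nTraitGenes = 8,
                                  nBackgroundGenes = 30,
                                  causalLoading = 0.5, noiseSd = 0.3,
                                  seed = 52))
  tr <- groundTruth(te)
  part <- partitionPhenotype(phenotype(te), 3, 14)
  rep_ <- groupConsistency(te, part, candidates = tr$causal_transcripts)
  expect_identical(nrow(rep_@groupSummaries), 3L)
  expect_true(rep_@nodeConsistency >= 0 && rep_@nodeConsistency <= 100)
  expect_true(rep_@edgeConsistency >= 0 && rep_@edgeConsistency <= 100)
  expect_identical(length(rep_@networks), 3L)
  expect_true(all(vapply(rep_@networks, pCutoff, 0) == 0.01))
  # groups are phenotype-separated by construction of the generator
  expect_lt(rep_@anova$p, 0.01)
})
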