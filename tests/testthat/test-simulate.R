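test_that("config validation rejects degenerate worlds", {
  expect_error(simConfig(nSamples = 3), "nSamples")
  expect_error(simConfig(traitMultiProb = 1.2), "\\[0,1\\]")
  expect_error(simConfig(causalLoading = 1), "causalLoading")
  expect_error(simConfig(causalLoading = 0.9, noiseSd = 0.9), "attainable")
  expect_error(simConfig(nTissues = 1), "nTissues")
  expect_error(simConfig(causalPerGeneRange = c(4, 1)), "causalPerGeneRange")
})

test_that("identical config and seed give byte-identical output", {
  cfg <- simConfig(nSamples = 12, nBackgroundGenes = 20, seed = 99)
  a <- simulateDataset(cfg)
  b <- simulateDataset(cfg)
  expect_identical(abundance(a), abundance(b))
  expect_identical(phenotype(a), phenotype(b))
  expect_identical(groundTruth(a), groundTruth(b))
  c <- simulateDataset(simConfig(nSamples = 12, nBackgroundGenes = 20,
                                 seed = 100))
  expect_false(identical(abundance(a), abundance(c)))
})

test_that("expression is strictly positive with no NaN, truth is coherent", {
  te <- simulateDataset(simConfig(nSamples = 10, nBackgroundGenes = 30,
                                  seed = 3))
  a <- abundance(te)
  expect_true(all(is.finite(a)) && all(a > 0))
  tr <- groundTruth(te)
  expect_true(all(tr$causal_transcripts %in% tr$trait_transcripts))
  counts <- tr$per_gene_transcript_counts
  gm <- geneMap(te)
  tab <- table(gm$gene_id)
  expect_identical(as.integer(counts[names(tab)]), as.integer(tab))
  # causal per gene within range and <= gene transcript count
  causalGene <- sub("_t[0-9]+$", "", tr$causal_transcripts)
  perGene <- table(causalGene)
  expect_true(all(perGene >= 1 & perGene <= 4))
  expect_true(all(perGene <= counts[names(perGene)]))
})

test_that("causal loading controls the planted correlation", {
  # no signal: mean |cor| with phenotype stays near zero across seeds
  rs <- sapply(1:5, function(s) {
    te <- simulateDataset(simConfig(nSamples = 60, nTraitGenes = 5,
                                    nBackgroundGenes = 5,
                                    causalLoading = 0, seed = s))
    tr <- groundTruth(te)
    mean(abs(cor(t(log(abundance(te)[tr$causal_transcripts, , drop = FALSE])),
                 phenotype(te))))
  })
  expect_lt(mean(rs), 0.2)

  # noiseless limit: causal transcripts track the latent factor exactly
  te <- simulateDataset(simConfig(nSamples = 20, nTraitGenes = 4,
                                  nBackgroundGenes = 2, causalLoading = 0.9,
                                  noiseSd = 0, seed = 5))
  tr <- groundTruth(te)
  rs <- cor(t(log(abundance(te)[tr$causal_transcripts, , drop = FALSE])),
            tr$latent_factor)
  expect_true(all(abs(rs - 1) < 1e-10))
})

test_that("planted correlation matches a Monte-Carlo oracle of the model", {
  # oracle: 1e6 draws from the generative model itself, written out long-hand
  beta <- 0.6; sdN <- 0.5
  sigmaY2 <- 1 / (beta^2 + sdN^2) - 1
  set.seed(424242)
  f <- rnorm(1e6)
  y <- f + rnorm(1e6, sd = sqrt(sigmaY2))
  x <- beta * f + rnorm(1e6, sd = sdN)
  popR <- cor(x, y)
  expect_equal(popR, 0.6, tolerance = 0.01)  # design identity of the model

  te <- simulateDataset(simConfig(nSamples = 100, causalLoading = 0.6,
                                  nBackgroundGenes = 10, seed = 1))
  tr <- groundTruth(te)
  meanR <- mean(cor(t(log(abundance(te)[tr$causal_transcripts, ])),
                    phenotype(te)))
  expect_lt(abs(meanR - popR), 0.1)
})

test_that("simulated homology tables round-trip through the filter", {
  te <- simulateDataset(simConfig(nSamples = 10, nTraitGenes = 6,
                                  nBackgroundGenes = 3, seed = 11))
  gm <- geneMap(te)
  map <- gm[gm$is_trait, c("gene_id", "transcript_id", "identity_pct")]

  tab0 <- simulateBlastTable(map, decoyCount = 0, seed = 2)
  got <- buildGeneMap(filterHits(tab0))
  got <- got[order(got$gene_id, got$transcript_id),
             c("gene_id", "transcript_id")]
  rownames(got) <- NULL
  exp_ <- map[order(map$gene_id, map$transcript_id),
              c("gene_id", "transcript_id")]
  rownames(exp_) <- NULL
  expect_identical(got, exp_)

  tab <- simulateBlastTable(map, decoyCount = 13, seed = 2)
  expect_identical(sum(tab$is_decoy), 13L)
  kept <- filterHits(tab)
  expect_true(all(!kept$is_decoy))
  expect_identical(nrow(kept), nrow(map))
  # every decoy violates at least one threshold
  dec <- tab[tab$is_decoy, ]
  expect_true(all(dec$pident < 90 | dec$length < 300 | dec$evalue > 1e-6))
  # determinism
  expect_identical(tab, simulateBlastTable(map, decoyCount = 13, seed = 2))
})

test_that("tissue panel exercises the two-or-more-tissues filter", {
  cfg <- simConfig(nSamples = 10, nTraitGenes = 4, nBackgroundGenes = 30,
                   nTissues = 14, seed = 8)
  all1 <- simulateTissuePanel(cfg, singleTissueFrac = 1)
  expect_true(all(rowSums(abundance(all1) > 0) <= 1))

  def <- simulateTissuePanel(cfg)
  tr <- groundTruth(def)
  expect_true(all(rowSums(abundance(def)[tr$trait_transcripts, ] > 0) >= 2))
  expect_identical(abundance(def), abundance(simulateTissuePanel(cfg)))
})

test_that("with no shared tissue profile the trait arm matches the null", {
  # planted loading 0: the tendency t-test should not separate the arms
  rejections <- sapply(1:20, function(s) {
    cfg <- simConfig(nSamples = 10, nTraitGenes = 8, nBackgroundGenes = 60,
                     nTissues = 14, seed = 1000 + s)
    te <- simulateTissuePanel(cfg, singleTissueFrac = 0, profileLoading = 0)
    tr <- groundTruth(te)
    bg <- setdiff(rownames(abundance(te)), tr$trait_transcripts)
    prof <- tendencyProfile(abundance(te), tr$trait_transcripts, bg,
                            k = 10, pGrid = 0.01, replications = 50,
                            seed = s)
    tt <- tendencyTests(prof)
    any(tt$p[tt$measure == "edges"] <= 0.01)
  })
  expect_gte(mean(!rejections), 0.9)
})

test_that("the correlation screen recovers planted causal transcripts", {
  hit <- sapply(1:20, function(s) {
    te <- simulateDataset(simConfig(nSamples = 100, nTraitGenes = 8,
                                    nBackgroundGenes = 10,
                                    causalLoading = 0.6, seed = 2000 + s))
    tr <- groundTruth(te)
    res <- correlateTrait(te)
    mean(res$significant[res$transcript_id %in% tr$causal_transcripts])
  })
  expect_gte(mean(hit), 0.95)
})
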