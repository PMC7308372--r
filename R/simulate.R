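#' Build a simulation configuration
#'
#' Defaults describe a desk-scale stand-in for a quantitative-trait
#' expression study: a 42-line genotype panel, 10 published trait genes of
#' which ~90\% are alternatively spliced into multiple transcripts (about
#' 6.7 transcripts per trait gene on average), a 1000-gene background, and
#' 1--4 causal transcripts per trait gene loading on a latent trait factor
#' with population correlation 0.6 to the phenotype.
#'
#' @param nSamples genotypes/lines in the panel.
#' @param nTraitGenes number of trait genes.
#' @param nBackgroundGenes number of background genes.
#' @param traitMultiProb probability a trait gene has >= 2 transcripts.
#' @param backgroundMultiProb same for background genes.
#' @param transcriptDistMean Poisson mean of extra transcripts for
#'   multi-transcript genes.
#' @param causalPerGeneRange inclusive range of causal transcripts per trait
#'   gene.
#' @param causalLoading target population correlation between causal
#'   transcript log expression and phenotype, in [0,1).
#' @param noiseSd residual sd of log expression.
#' @param nTissues 0 for genotype mode, >= 2 for the multi-tissue mode.
#' @param seed RNG seed.
#' @return a validated \linkS4class{SimulationConfig}.
#' @export
simConfig <- function(nSamples = 42L, nTraitGenes = 10L,
                      nBackgroundGenes = 1000L,
                      traitMultiProb = 0.9, backgroundMultiProb = 0.5,
                      transcriptDistMean = 6.3,
                      causalPerGeneRange = c(1L, 4L),
                      causalLoading = 0.6, noiseSd = 0.5,
                      nTissues = 0L, seed = 1L) {
  new("SimulationConfig",
      nSamples = as.integer(nSamples),
      nTraitGenes = as.integer(nTraitGenes),
      nBackgroundGenes = as.integer(nBackgroundGenes),
      traitMultiProb = traitMultiProb,
      backgroundMultiProb = backgroundMultiProb,
      transcriptDistMean = transcriptDistMean,
      causalPerGeneRange = as.integer(causalPerGeneRange),
      causalLoading = causalLoading,
      noiseSd = noiseSd,
      nTissues = as.integer(nTissues),
      seed = as.integer(seed))
}

# transcript counts per gene: 1 + Bernoulli(multiProb) * Poisson(mean)
.drawTranscriptCounts <- function(n, multiProb, distMean) {
  1L + stats::rbinom(n, 1L, multiProb) * stats::rpois(n, distMean)
}

.transcriptIds <- function(geneIds, counts) {
  unlist(mapply(function(g, k) sprintf("%s_t%02d", g, seq_len(k)),
                geneIds, counts, SIMPLIFY = FALSE), use.names = FALSE)
}

#' Simulate a genotype-panel trait-expression dataset
#'
#' Generates a latent trait factor f ~ N(0,1) per genotype, a phenotype
#' y = f + e with e ~ N(0, s_y^2) where s_y is chosen so that causal
#' transcripts attain the target population correlation
#' \code{causalLoading} with y, causal transcript log expression
#' b*f + N(0, noiseSd^2) with b = \code{causalLoading}, and independent
#' N(0, noiseSd^2) log expression for every other transcript. Abundance is
#' exp(log expression), hence strictly positive. Per-gene transcript counts
#' follow 1 + Bernoulli(multiProb) * Poisson(transcriptDistMean), with trait
#' genes enriched for the multi-transcript state.
#'
#' @param config a \linkS4class{SimulationConfig} (genotype mode,
#'   \code{nTissues == 0}).
#' @return a \linkS4class{TraitExperiment}; ground truth is in
#'   \code{groundTruth()}, the gene/transcript catalog in \code{geneMap()}.
#' @examples
#' te <- simulateDataset(simConfig(nSamples = 20, nBackgroundGenes = 50))
#' dim(abundance(te))
#' @export
simulateDataset <- function(config) {
  validObject(config)
  set.seed(config@seed)
  n <- config@nSamples

  traitGenes <- sprintf("TG%04d", seq_len(config@nTraitGenes))
  bgGenes <- sprintf("BG%05d", seq_len(config@nBackgroundGenes))
  traitCounts <- .drawTranscriptCounts(config@nTraitGenes,
                                       config@traitMultiProb,
                                       config@transcriptDistMean)
  bgCounts <- .drawTranscriptCounts(config@nBackgroundGenes,
                                    config@backgroundMultiProb,
                                    config@transcriptDistMean)
  names(traitCounts) <- traitGenes
  names(bgCounts) <- bgGenes

  traitTx <- .transcriptIds(traitGenes, traitCounts)
  bgTx <- .transcriptIds(bgGenes, bgCounts)
  geneOfTx <- c(rep(traitGenes, traitCounts), rep(bgGenes, bgCounts))
  allTx <- c(traitTx, bgTx)

  # causal transcripts: the leading 1-4 (capped) transcripts of each trait gene
  rng <- config@causalPerGeneRange
  nCausal <- pmin(sample(seq(rng[1], rng[2]), config@nTraitGenes, replace = TRUE),
                  traitCounts)
  causalTx <- unlist(mapply(function(g, k) sprintf("%s_t%02d", g, seq_len(k)),
                            traitGenes, nCausal, SIMPLIFY = FALSE),
                     use.names = FALSE)

  beta <- config@causalLoading
  sd2 <- config@noiseSd^2
  # phenotype noise so that cor(causal log-expr, y) = beta:
  # cor = beta / sqrt((beta^2 + sd2) * (1 + sigmaY2)) = beta
  denom <- beta^2 + sd2
  sigmaY2 <- if (denom > 0) max(1 / denom - 1, 0) else 1

  f <- stats::rnorm(n)
  y <- f + stats::rnorm(n, sd = sqrt(sigmaY2))
  # report the trait on a positive mg/g-like scale; affine, so correlations
  # and group structure are unchanged (population mean 20, sd 4)
  y <- 20 + 4 * y / sqrt(1 + sigmaY2)

  logExpr <- matrix(stats::rnorm(length(allTx) * n, sd = config@noiseSd),
                    nrow = length(allTx), dimnames = list(allTx, NULL))
  ci <- match(causalTx, allTx)
  logExpr[ci, ] <- logExpr[ci, ] + matrix(beta * f, nrow = length(ci),
                                          ncol = n, byrow = TRUE)
  expr <- exp(logExpr)
  samples <- sprintf("S%03d", seq_len(n))
  colnames(expr) <- samples

  identity <- round(stats::runif(length(allTx), 90, 100), 1)
  rowDat <- S4Vectors::DataFrame(
    gene_id = geneOfTx,
    is_trait = allTx %in% traitTx,
    is_causal = allTx %in% causalTx,
    identity_pct = identity,
    row.names = allTx)
  colDat <- S4Vectors::DataFrame(phenotype = y, latent_factor = f,
                                 row.names = samples)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = expr), rowData = rowDat, colData = colDat)
  te <- new("TraitExperiment", se)
  metadata(te)$config <- config
  metadata(te)$truth <- list(
    causal_transcripts = causalTx,
    trait_transcripts = traitTx,
    per_gene_transcript_counts = c(traitCounts, bgCounts),
    latent_factor = stats::setNames(f, samples))
  validObject(te)
  te
}

#' Simulate a tabular homology-hit table for a gene/transcript catalog
#'
#' Emits one hit per true (gene, transcript) pair that passes the standard
#' homology filter (alignment length >= 300 bp, identity >= 90\%, E-value
#' <= 1e-6) plus \code{decoyCount} decoy hits that each violate exactly one
#' of the three thresholds (cycling through them), so that filter failures
#' localize. Column order follows the 12-column tabular output convention
#' (qseqid, sseqid, pident, length, mismatch, gapopen, qstart, qend, sstart,
#' send, evalue, bitscore); an extra logical column \code{is_decoy} records
#' the planted rows and is dropped by \code{\link{writeBlastTable}}.
#'
#' @param map data.frame with columns gene_id, transcript_id, identity_pct
#'   (identities must pass the filter for the round trip to be exact).
#' @param decoyCount number of planted failing hits.
#' @param seed RNG seed.
#' @return data.frame of hits with attribute column \code{is_decoy}.
#' @export
simulateBlastTable <- function(map, decoyCount = 0L, seed = 1L) {
  stopifnot(nrow(map) >= 1L,
            all(c("gene_id", "transcript_id", "identity_pct") %in% names(map)))
  set.seed(as.integer(seed))
  n <- nrow(map)
  len <- sample(300:2000, n, replace = TRUE)
  true <- data.frame(
    qseqid = map$gene_id, sseqid = map$transcript_id,
    pident = map$identity_pct, length = len,
    mismatch = round(len * (100 - map$identity_pct) / 100),
    gapopen = stats::rpois(n, 1),
    qstart = 1L, qend = len, sstart = 1L, send = len,
    evalue = 10^stats::runif(n, -50, -6.5),
    bitscore = round(len * 1.8), is_decoy = FALSE,
    stringsAsFactors = FALSE)
  if (decoyCount > 0L) {
    which3 <- rep_len(1:3, decoyCount)  # 1 identity, 2 length, 3 evalue
    dlen <- ifelse(which3 == 2L, sample(30:299, decoyCount, replace = TRUE),
                   sample(300:2000, decoyCount, replace = TRUE))
    decoy <- data.frame(
      qseqid = sample(unique(map$gene_id), decoyCount, replace = TRUE),
      sseqid = sprintf("DEC%05d_t01", seq_len(decoyCount)),
      pident = ifelse(which3 == 1L,
                      round(stats::runif(decoyCount, 50, 89.9), 1),
                      round(stats::runif(decoyCount, 90, 100), 1)),
      length = dlen,
      mismatch = 0L, gapopen = 0L, qstart = 1L, qend = dlen,
      sstart = 1L, send = dlen,
      evalue = ifelse(which3 == 3L, 10^stats::runif(decoyCount, -5.9, -1),
                      10^stats::runif(decoyCount, -50, -6.5)),
      bitscore = round(dlen * 1.8), is_decoy = TRUE,
      stringsAsFactors = FALSE)
    true <- rbind(true, decoy)
  }
  rownames(true) <- NULL
  true
}

#' Simulate a multi-tissue expression panel of a single plant
#'
#' One genotype, \code{nTissues} tissues. Trait transcripts share a latent
#' tissue profile (log expression = loading * profile + noise), so they are
#' co-expressed across tissues; background transcripts are independent
#' noise. A configurable fraction of transcripts is expressed in exactly one
#' tissue (zero elsewhere) to exercise the downstream rule that a transcript
#' must be expressed in two or more tissues to enter correlation analysis.
#' The masked set is drawn from background transcripts first and spills into
#' trait transcripts only when the fraction exceeds the background share, so
#' at default settings every planted trait transcript passes the filter.
#'
#' @param config \linkS4class{SimulationConfig} with \code{nTissues >= 2}.
#' @param singleTissueFrac fraction of transcripts confined to one tissue.
#' @param profileLoading loading of trait transcripts on the shared tissue
#'   profile; defaults to \code{config@causalLoading}. 0 removes the shared
#'   structure entirely.
#' @return a \linkS4class{TraitExperiment} whose columns are tissues
#'   (phenotype is NA: there is no per-tissue trait value).
#' @export
simulateTissuePanel <- function(config, singleTissueFrac = 0.1,
                                profileLoading = config@causalLoading) {
  validObject(config)
  if (config@nTissues < 2L)
    stop("tissue mode requires nTissues >= 2")
  stopifnot(singleTissueFrac >= 0, singleTissueFrac <= 1)
  set.seed(config@seed)
  nT <- config@nTissues

  traitGenes <- sprintf("TG%04d", seq_len(config@nTraitGenes))
  bgGenes <- sprintf("BG%05d", seq_len(config@nBackgroundGenes))
  traitCounts <- .drawTranscriptCounts(config@nTraitGenes,
                                       config@traitMultiProb,
                                       config@transcriptDistMean)
  bgCounts <- .drawTranscriptCounts(config@nBackgroundGenes,
                                    config@backgroundMultiProb,
                                    config@transcriptDistMean)
  names(traitCounts) <- traitGenes
  names(bgCounts) <- bgGenes
  traitTx <- .transcriptIds(traitGenes, traitCounts)
  bgTx <- .transcriptIds(bgGenes, bgCounts)
  allTx <- c(traitTx, bgTx)
  geneOfTx <- c(rep(traitGenes, traitCounts), rep(bgGenes, bgCounts))

  prof <- stats::rnorm(nT)
  logExpr <- matrix(stats::rnorm(length(allTx) * nT, sd = config@noiseSd),
                    nrow = length(allTx), dimnames = list(allTx, NULL))
  ti <- seq_along(traitTx)
  logExpr[ti, ] <- logExpr[ti, ] + matrix(profileLoading * prof,
                                          nrow = length(ti), ncol = nT,
                                          byrow = TRUE)
  expr <- exp(logExpr)

  nMask <- round(singleTissueFrac * length(allTx))
  if (nMask > 0L) {
    bgOrder <- sample(seq_along(bgTx)) + length(traitTx)
    trOrder <- sample(seq_along(traitTx))
    maskIdx <- c(bgOrder, trOrder)[seq_len(nMask)]
    keepTissue <- sample.int(nT, length(maskIdx), replace = TRUE)
    for (j in seq_along(maskIdx)) {
      keep <- expr[maskIdx[j], keepTissue[j]]
      expr[maskIdx[j], ] <- 0
      expr[maskIdx[j], keepTissue[j]] <- keep
    }
  }
  tissues <- sprintf("T%02d", seq_len(nT))
  colnames(expr) <- tissues

  rowDat <- S4Vectors::DataFrame(
    gene_id = geneOfTx,
    is_trait = allTx %in% traitTx,
    is_causal = FALSE,
    identity_pct = round(stats::runif(length(allTx), 90, 100), 1),
    row.names = allTx)
  colDat <- S4Vectors::DataFrame(phenotype = NA_real_,
                                 shared_profile = prof, row.names = tissues)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = expr), rowData = rowDat, colData = colDat)
  te <- new("TraitExperiment", se)
  metadata(te)$config <- config
  metadata(te)$truth <- list(
    causal_transcripts = character(),
    trait_transcripts = traitTx,
    per_gene_transcript_counts = c(traitCounts, bgCounts),
    latent_factor = stats::setNames(prof, tissues))
  te
}
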