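#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Simulation configuration for synthetic trait-gene expression data
#'
#' Holds every tunable of the synthetic-data generator: population size,
#' numbers of trait and background genes, the per-gene transcript-count
#' model, the planted causal structure linking transcripts to the phenotype,
#' and the RNG seed. The generator emulates a quantitative-trait study in
#' which a panel of genotypes is phenotyped for a continuously varying trait
#' (ginsenoside content, fiber length, grain yield, ...) and transcript-level
#' expression is quantified by RNA-seq in one tissue.
#'
#' @slot nSamples integer, number of genotypes/lines in the population.
#' @slot nTraitGenes integer, number of published trait genes.
#' @slot nBackgroundGenes integer, number of background ("unknown") genes.
#' @slot traitMultiProb probability that a trait gene is alternatively
#'   spliced into two or more transcripts.
#' @slot backgroundMultiProb same probability for background genes.
#' @slot transcriptDistMean Poisson mean of extra transcripts for
#'   multi-transcript genes; transcript count per gene is
#'   \code{1 + Bernoulli(multiProb) * Poisson(transcriptDistMean)}.
#' @slot causalPerGeneRange inclusive integer range of causal transcripts
#'   per trait gene (default 1--4, capped at the gene's transcript count).
#' @slot causalLoading correlation-scale loading in [0,1): the target
#'   population correlation between a causal transcript's log expression and
#'   the phenotype.
#' @slot noiseSd residual standard deviation of log expression.
#' @slot nTissues number of tissues for the single-plant multi-tissue mode;
#'   0 selects the genotype-panel mode.
#' @slot seed integer RNG seed; identical config + seed gives byte-identical
#'   output.
#' @export
setClass("SimulationConfig", representation(
  nSamples = "integer",
  nTraitGenes = "integer",
  nBackgroundGenes = "integer",
  traitMultiProb = "numeric",
  backgroundMultiProb = "numeric",
  transcriptDistMean = "numeric",
  causalPerGeneRange = "integer",
  causalLoading = "numeric",
  noiseSd = "numeric",
  nTissues = "integer",
  seed = "integer"
))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nSamples < 4L)
    msg <- c(msg, "nSamples must be >= 4 (correlation p-values are degenerate below)")
  if (object@nTraitGenes < 1L) msg <- c(msg, "nTraitGenes must be >= 1")
  if (object@nBackgroundGenes < 1L) msg <- c(msg, "nBackgroundGenes must be >= 1")
  for (p in c("traitMultiProb", "backgroundMultiProb")) {
    v <- slot(object, p)
    if (!is.finite(v) || v < 0 || v > 1) msg <- c(msg, paste(p, "must be in [0,1]"))
  }
  if (object@transcriptDistMean < 0) msg <- c(msg, "transcriptDistMean must be >= 0")
  r <- object@causalPerGeneRange
  if (length(r) != 2L || any(r < 1L) || r[1] > r[2])
    msg <- c(msg, "causalPerGeneRange must be an increasing pair of integers >= 1")
  if (!is.finite(object@causalLoading) || object@causalLoading < 0 ||
      object@causalLoading >= 1)
    msg <- c(msg, "causalLoading must be in [0, 1)")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@causalLoading^2 + object@noiseSd^2 > 1)
    msg <- c(msg, "causalLoading^2 + noiseSd^2 must be <= 1 for the target correlation to be attainable")
  if (object@nTissues != 0L && object@nTissues < 2L)
    msg <- c(msg, "nTissues must be 0 (genotype mode) or >= 2 (tissue mode)")
  if (length(msg)) msg else TRUE
})

#' Container for a simulated (or assembled) trait-expression experiment
#'
#' A \linkS4class{SummarizedExperiment} with one assay, \code{"abundance"}
#' (transcripts x samples, strictly positive abundance on the FPKM/TPM-like
#' scale), per-transcript \code{rowData} columns \code{gene_id},
#' \code{is_trait}, \code{is_causal} and \code{identity_pct}, and the trait
#' value in \code{colData$phenotype}. Ground truth (causal transcript set,
#' latent factor) and the generating \linkS4class{SimulationConfig} live in
#' \code{metadata()}.
#'
#' @export
setClass("TraitExperiment", contains = "SummarizedExperiment")

setValidity("TraitExperiment", function(object) {
  msg <- character()
  if (!"abundance" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'abundance' is required")
  else {
    a <- SummarizedExperiment::assay(object, "abundance")
    if (any(!is.finite(a))) msg <- c(msg, "abundance values must be finite")
    else if (any(a < 0)) msg <- c(msg, "abundance values must be non-negative")
  }
  if (!"phenotype" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData column 'phenotype' is required")
  if (!"gene_id" %in% colnames(SummarizedExperiment::rowData(object)))
    msg <- c(msg, "rowData column 'gene_id' is required")
  if (length(msg)) msg else TRUE
})

#' Hard-threshold co-expression network over a transcript set
#'
#' An undirected graph whose nodes are candidate transcripts and whose edges
#' join transcript pairs with a two-tailed expression-correlation p-value at
#' or below the cutoff. Edges carry the correlation \code{r} and its
#' \code{p}; the candidate set is retained so that isolated candidates are
#' distinguishable from transcripts never considered.
#'
#' @slot candidates character, transcripts the network was built over.
#' @slot edges data.frame with columns node_a, node_b, r, p; node_a < node_b.
#' @slot cutoff numeric, the p-value threshold applied.
#' @slot nSamples integer, number of samples underlying the correlations.
#' @export
setClass("CoexpressionNetwork", representation(
  candidates = "character",
  edges = "data.frame",
  cutoff = "numeric",
  nSamples = "integer"
))

setValidity("CoexpressionNetwork", function(object) {
  e <- object@edges
  msg <- character()
  need <- c("node_a", "node_b", "r", "p")
  if (!all(need %in% names(e))) {
    msg <- c(msg, "edges must have columns node_a, node_b, r, p")
    return(msg)
  }
  if (nrow(e)) {
    if (any(e$node_a == e$node_b)) msg <- c(msg, "self-edges are not allowed")
    if (any(e$node_a > e$node_b)) msg <- c(msg, "edges must be stored with node_a < node_b")
    if (anyDuplicated(paste(e$node_a, e$node_b))) msg <- c(msg, "duplicate edges")
    if (any(e$p > object@cutoff + 1e-12)) msg <- c(msg, "edge p exceeds cutoff")
    if (!all(c(e$node_a, e$node_b) %in% object@candidates))
      msg <- c(msg, "edge endpoints must be candidate transcripts")
  }
  if (length(msg)) msg else TRUE
})

#' Network-formation tendency of a trait set against a bootstrap null
#'
#' For each p-value cutoff on a decreasing grid and each arm (trait,
#' random), stores the replicate-wise node and edge counts of networks built
#' from bootstrap-sampled size-k transcript subsets, their mean and standard
#' deviation, and the two-tailed Student's t comparison between arms.
#'
#' @slot profile data.frame: cutoff, measure, arm, mean, sd, n.
#' @slot tests data.frame: cutoff, measure, t, p, degenerate flag.
#' @slot replicates list of per-arm arrays of replicate counts
#'   (cutoff x replicate), for measures "nodes" and "edges".
#' @slot pGrid numeric, strictly decreasing cutoffs.
#' @slot replications integer, bootstrap replications per arm.
#' @slot k integer, subset size sampled per replicate.
#' @slot seed integer, RNG seed used.
#' @export
setClass("NullTendencyProfile", representation(
  profile = "data.frame",
  tests = "data.frame",
  replicates = "list",
  pGrid = "numeric",
  replications = "integer",
  k = "integer",
  seed = "integer"
))

setValidity("NullTendencyProfile", function(object) {
  msg <- character()
  if (any(diff(object@pGrid) >= 0)) msg <- c(msg, "pGrid must be strictly decreasing")
  if (object@replications < 2L) msg <- c(msg, "replications must be >= 2")
  if (nrow(object@profile) && any(object@profile$sd < 0)) msg <- c(msg, "sd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Equal-size phenotype groups of a genotype panel
#'
#' Samples sorted by ascending phenotype and split into contiguous groups of
#' fixed size; excess samples are dropped symmetrically from around the
#' overall median before grouping.
#'
#' @slot groups named list of character sample-ID vectors, ascending by
#'   group phenotype mean.
#' @slot stats data.frame: group, n, mean, sd.
#' @slot dropped character, sample IDs excluded by the drop rule.
#' @slot phenotype named numeric, the phenotype of every retained sample.
#' @export
setClass("GroupPartition", representation(
  groups = "list",
  stats = "data.frame",
  dropped = "character",
  phenotype = "numeric"
))

setValidity("GroupPartition", function(object) {
  g <- object@groups
  msg <- character()
  if (length(g) < 1L) msg <- c(msg, "at least one group required")
  ids <- unlist(g, use.names = FALSE)
  if (anyDuplicated(ids)) msg <- c(msg, "groups must be disjoint")
  if (length(unique(lengths(g))) > 1L) msg <- c(msg, "groups must have equal sizes")
  if (length(g) > 1L) {
    ph <- object@phenotype
    for (i in seq_len(length(g) - 1L)) {
      if (max(ph[g[[i]]]) > min(ph[g[[i + 1L]]]) + 1e-12)
        msg <- c(msg, "groups must be ordered: max(G_i) <= min(G_{i+1})")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Cross-group network consistency report
#'
#' Per-phenotype-group network summaries together with the node and edge
#' consistency percentages across groups, the one-way ANOVA + LSD separation
#' of the group phenotypes, and the pairwise percent differences of group
#' means.
#'
#' @slot groupSummaries data.frame: group, n_nodes, n_edges.
#' @slot nodeConsistency numeric percentage in [0,100].
#' @slot edgeConsistency numeric percentage in [0,100].
#' @slot anova list with F, df_between, df_within, p, letters.
#' @slot percentDiffs data.frame of pairwise percent differences plus the
#'   min--max range as attributes.
#' @slot networks list of \linkS4class{CoexpressionNetwork}, one per group.
#' @slot method character, consistency denominator convention used
#'   ("iou" or "candidate").
#' @export
setClass("ConsistencyReport", representation(
  groupSummaries = "data.frame",
  nodeConsistency = "numeric",
  edgeConsistency = "numeric",
  anova = "list",
  percentDiffs = "data.frame",
  networks = "list",
  method = "character"
))
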