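#' @describeIn TraitExperiment-class the abundance matrix (transcripts x samples).
#' @export
setMethod("abundance", "TraitExperiment", function(x)
  SummarizedExperiment::assay(x, "abundance"))

#' @describeIn TraitExperiment-class named numeric phenotype per sample.
#' @export
setMethod("phenotype", "TraitExperiment", function(x) {
  cd <- SummarizedExperiment::colData(x)
  stats::setNames(cd$phenotype, rownames(cd))
})

#' @describeIn TraitExperiment-class the gene/transcript catalog as a
#'   data.frame (gene_id, transcript_id, identity_pct, is_trait).
#' @export
setMethod("geneMap", "TraitExperiment", function(x) {
  rd <- SummarizedExperiment::rowData(x)
  data.frame(gene_id = rd$gene_id, transcript_id = rownames(rd),
             identity_pct = rd$identity_pct, is_trait = rd$is_trait,
             stringsAsFactors = FALSE)
})

#' @describeIn TraitExperiment-class ground-truth labels from the generator
#'   (causal/trait transcript sets, per-gene counts, latent factor).
#' @export
setMethod("groundTruth", "TraitExperiment", function(x) metadata(x)$truth)

#' @describeIn CoexpressionNetwork-class the edge table (node_a, node_b, r, p).
#' @export
setMethod("networkEdges", "CoexpressionNetwork", function(x) x@edges)

#' @describeIn CoexpressionNetwork-class node set; by default the
#'   non-isolated (edge-participating) transcripts, the convention used for
#'   all tendency statistics. \code{isolated = TRUE} returns the full
#'   candidate set instead.
#' @param isolated include isolated candidate transcripts.
#' @export
setMethod("networkNodes", "CoexpressionNetwork",
          function(x, isolated = FALSE) {
  if (isolated) x@candidates
  else sort(unique(c(x@edges$node_a, x@edges$node_b)))
})

#' @describeIn CoexpressionNetwork-class candidate transcripts the network
#'   was built over.
#' @export
setMethod("candidateSet", "CoexpressionNetwork", function(x) x@candidates)

#' @describeIn CoexpressionNetwork-class the p-value cutoff applied.
#' @export
setMethod("pCutoff", "CoexpressionNetwork", function(x) x@cutoff)

#' @describeIn GroupPartition-class named list of sample IDs per group.
#' @export
setMethod("phenotypeGroups", "GroupPartition", function(x) x@groups)

#' @describeIn NullTendencyProfile-class per-cutoff/arm/measure mean, sd, n.
#' @export
setMethod("tendencyTable", "NullTendencyProfile", function(x) x@profile)

#' @describeIn NullTendencyProfile-class per-cutoff/measure t statistics and
#'   two-tailed p-values for the trait vs random comparison.
#' @export
setMethod("tendencyTests", "NullTendencyProfile", function(x) x@tests)

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:",
      object@nSamples, "samples,",
      object@nTraitGenes, "trait genes,",
      object@nBackgroundGenes, "background genes\n")
  cat("  causal loading", object@causalLoading,
      "| noise sd", object@noiseSd,
      "| causal per gene", paste(object@causalPerGeneRange, collapse = "-"),
      "\n")
  cat("  mode:", if (object@nTissues > 0L)
    paste0("tissue (", object@nTissues, " tissues)") else "genotype panel",
    "| seed", object@seed, "\n")
})

setMethod("show", "CoexpressionNetwork", function(object) {
  cat("CoexpressionNetwork: ", length(networkNodes(object)),
      " connected nodes (of ", length(object@candidates),
      " candidates), ", nrow(object@edges), " edges at P <= ",
      format(object@cutoff), "\n", sep = "")
})

setMethod("show", "NullTendencyProfile", function(object) {
  cat("NullTendencyProfile:", length(object@pGrid), "cutoffs,",
      object@replications, "replications per arm, k =", object@k, "\n")
  print(object@tests)
})

setMethod("show", "GroupPartition", function(object) {
  cat("GroupPartition:", length(object@groups), "groups of",
      length(object@groups[[1]]), "samples;",
      length(object@dropped), "dropped\n")
  print(object@stats)
})

setMethod("show", "ConsistencyReport", function(object) {
  cat("ConsistencyReport (", object@method, "): node consistency ",
      round(object@nodeConsistency, 1), "%, edge consistency ",
      round(object@edgeConsistency, 1), "%\n", sep = "")
  print(object@groupSummaries)
})
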