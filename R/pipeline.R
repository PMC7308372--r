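.stageOrder <- c("catalog", "splicing", "correlation", "network",
                 "tendency", "groups")

# named per-stage RNG substreams derived from the single run seed, so
# rerunning one stage never perturbs another's stream
.stageSeed <- function(seed, stage) {
  offsets <- c(simulate = 0L, blast = 11L, catalog = 23L, splicing = 37L,
               correlation = 41L, network = 53L, tendency = 67L,
               groups = 79L)
  (as.integer(seed) %% 21474836L) * 100L + offsets[[stage]]
}

.defaultRunConfig <- function() list(
  seed = 1L,
  output_dir = NULL,
  stages = .stageOrder,
  simulate = NULL,      # list of simConfig() arguments, or NULL
  expression = NULL,    # input paths when not simulating
  phenotype = NULL,
  gene_map = NULL,
  blast = NULL,
  background_counts = NULL,  # TSV gene_id, n_transcripts for splicing stage
  catalog = list(min_align_len = 300, min_identity = 90, max_evalue = 1e-6,
                 max_per_gene = 2, tie_window = 0.5),
  splicing = list(alpha = 0.01, correct = FALSE),
  correlation = list(method = "pearson", log_transform = TRUE,
                     alpha = 0.05, adjust = "none"),
  network = list(p_cutoff = 0.05, min_expressed = 0),
  tendency = list(k = NULL, p_grid = defaultPGrid(), replications = 100,
                  background_pool_size = 200, connectivity_cutoffs =
                    c(0.05, 0.01, 0.001)),
  groups = list(n_groups = 3, group_size = NULL, p_cutoff = 0.01,
                alpha = 0.01, consistency = "iou"))

.mergeConfig <- function(config) {
  def <- .defaultRunConfig()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown))
    stop("unknown run-config keys: ", paste(unknown, collapse = ", "))
  for (nm in names(config)) {
    if (is.list(def[[nm]]) && is.list(config[[nm]]) &&
        !is.null(names(def[[nm]]))) {
      unknown2 <- setdiff(names(config[[nm]]), names(def[[nm]]))
      if (length(unknown2) && nm != "simulate")
        stop("unknown keys in run-config section '", nm, "': ",
             paste(unknown2, collapse = ", "))
      def[[nm]][names(config[[nm]])] <- config[[nm]]
    } else {
      def[[nm]] <- config[[nm]]
    }
  }
  def
}

.runStage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full quantitative-trait gene analysis pipeline
#'
#' Executes catalog -> splicing enrichment -> trait correlation ->
#' co-expression network -> network tendency -> phenotype groups in order,
#' on either a simulated dataset (\code{config$simulate} holds
#' \code{\link{simConfig}} arguments) or on input files
#' (\code{config$expression}, \code{config$phenotype},
#' \code{config$gene_map} and optionally \code{config$blast}). Stages can
#' be skipped via \code{config$stages}. All randomness flows from
#' \code{config$seed} through named per-stage substreams. The returned
#' report echoes every parameter and is written as JSON (plus per-stage
#' TSV/GraphML outputs) to \code{config$output_dir} when set; it is
#' deterministic for a fixed config apart from the \code{timestamp} field.
#'
#' @param config nested list (unknown keys are rejected), or path to a
#'   JSON file holding one.
#' @return the run report, invisibly a list; written to
#'   \code{<output_dir>/report.json} when an output directory is set.
#' @export
runPipeline <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- .mergeConfig(config)
  stages <- match.arg(cfg$stages, .stageOrder, several.ok = TRUE)
  report <- list(
    package = "qtnet",
    version = as.character(utils::packageVersion("qtnet")),
    seed = cfg$seed,
    parameters = cfg[setdiff(names(cfg), "output_dir")],
    stages_run = stages)

  outDir <- cfg$output_dir
  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)
  emit <- function(writer, obj, file) {
    if (!is.null(outDir)) writer(obj, file.path(outDir, file))
  }

  # ---- inputs ----
  if (!is.null(cfg$simulate)) {
    simArgs <- cfg$simulate
    if (is.null(simArgs$seed)) simArgs$seed <- .stageSeed(cfg$seed, "simulate")
    scfg <- do.call(simConfig, simArgs)
    te <- .runStage("simulate", if (scfg@nTissues > 0L)
      simulateTissuePanel(scfg) else simulateDataset(scfg))
    expr <- abundance(te)
    pheno <- phenotype(te)
    trueMap <- geneMap(te)
    traitMap <- trueMap[trueMap$is_trait, , drop = FALSE]
    hits <- simulateBlastTable(traitMap, decoyCount = 20L,
                               seed = .stageSeed(cfg$seed, "blast"))
    emit(writeExpression, expr, "expression.tsv")
    if (!all(is.na(pheno))) emit(writePhenotype, pheno, "phenotype.tsv")
    emit(writeBlastTable, hits, "hits.tsv")
    bgCounts <- table(trueMap$gene_id[!trueMap$is_trait])
  } else {
    if (is.null(cfg$expression)) stop("config$expression is required")
    expr <- .runStage("catalog", readExpression(cfg$expression))
    pheno <- if (!is.null(cfg$phenotype)) readPhenotype(cfg$phenotype)
             else stop("phenotype file is required: config$phenotype is NULL")
    hits <- if (!is.null(cfg$blast)) readBlastTable(cfg$blast) else NULL
    trueMap <- if (!is.null(cfg$gene_map)) readGeneMap(cfg$gene_map) else NULL
    if (is.null(hits) && is.null(trueMap))
      stop("either config$blast or config$gene_map is required")
    bgCounts <- if (!is.null(cfg$background_counts)) {
      bc <- utils::read.delim(cfg$background_counts,
                              stringsAsFactors = FALSE)
      if (!all(c("gene_id", "n_transcripts") %in% names(bc)))
        stop("background_counts must have columns gene_id, n_transcripts")
      stats::setNames(as.integer(bc$n_transcripts), bc$gene_id)
    } else NULL
    te <- NULL
  }

  # ---- catalog ----
  map <- NULL
  if ("catalog" %in% stages) {
    map <- .runStage("catalog", {
      filtered <- if (!is.null(hits))
        filterHits(hits, cfg$catalog$min_align_len,
                   cfg$catalog$min_identity, cfg$catalog$max_evalue)
      else NULL
      m <- if (!is.null(filtered)) buildGeneMap(filtered)
           else trueMap[, c("gene_id", "transcript_id", "identity_pct")]
      reps <- selectRepresentatives(m, cfg$catalog$max_per_gene,
                                    cfg$catalog$tie_window)
      m$is_representative <- m$transcript_id %in% reps
      m
    })
    summ <- transcriptCountSummary(map)
    report$catalog <- list(
      n_genes = summ$n_genes, n_multi = summ$n_multi,
      n_single = summ$n_single, min = summ$min, max = summ$max,
      mean_transcripts_per_gene = summ$mean,
      n_representatives = sum(map$is_representative))
    emit(writeGeneMap, map, "gene_map.tsv")
  }
  if (is.null(map) && !is.null(trueMap))
    map <- trueMap[, c("gene_id", "transcript_id", "identity_pct")]
  if (is.null(map)) stop("downstream stages need a gene map; run 'catalog'")
  map <- map[map$transcript_id %in% rownames(expr), , drop = FALSE]
  traitTx <- map$transcript_id
  reps <- if ("is_representative" %in% names(map))
    map$transcript_id[map$is_representative] else traitTx

  # ---- splicing enrichment ----
  if ("splicing" %in% stages && is.null(bgCounts)) {
    report$splicing <- list(skipped = "no background transcript counts supplied")
  } else if ("splicing" %in% stages) {
    report$splicing <- .runStage("splicing", {
      cs <- transcriptCountSummary(map)
      bg <- backgroundFractions(bgCounts)
      et <- enrichmentTest(cs$n_multi, cs$n_single, bg$bg_multi_frac,
                           alpha = cfg$splicing$alpha,
                           correct = cfg$splicing$correct)
      et$bg <- bg
      et
    })
    emit(function(x, f) jsonlite::write_json(x, f, auto_unbox = TRUE,
                                             digits = NA),
         report$splicing, "splicing.json")
  }

  # ---- trait correlation ----
  corRes <- NULL
  if ("correlation" %in% stages && !all(is.na(pheno))) {
    corRes <- .runStage("correlation",
      correlateTrait(expr[traitTx, , drop = FALSE], pheno,
                     method = cfg$correlation$method,
                     logTransform = cfg$correlation$log_transform,
                     alpha = cfg$correlation$alpha,
                     adjust = cfg$correlation$adjust))
    pg <- perGeneSummary(corRes, map)
    report$correlation <- list(
      n_tested = nrow(corRes),
      n_significant = sum(corRes$significant),
      mean_significant_per_gene = pg$mean_significant,
      pooled_fraction = pg$pooled_fraction,
      genes_without_significant = pg$genes_without_significant)
    emit(function(x, f) utils::write.table(x, f, sep = "\t", quote = FALSE,
                                           row.names = FALSE),
         corRes, "correlation.tsv")
  }

  # ---- co-expression network ----
  nw <- NULL
  if ("network" %in% stages) {
    nw <- .runStage("network",
      buildNetwork(expr, candidates = reps,
                   pCutoff = cfg$network$p_cutoff,
                   method = cfg$correlation$method,
                   logTransform = cfg$correlation$log_transform,
                   minExpressed = cfg$network$min_expressed))
    ns <- networkSummary(nw)
    report$network <- c(ns, list(cutoff = cfg$network$p_cutoff,
                                 n_candidates = length(candidateSet(nw))))
    emit(writeNetwork, nw, "network.tsv")
    if (!is.null(outDir))
      writeNetwork(nw, file.path(outDir, "network.graphml"), "graphml")
  }

  # ---- tendency vs bootstrap null ----
  if ("tendency" %in% stages) {
    report$tendency <- .runStage("tendency", {
      bgTx <- setdiff(rownames(expr), traitTx)
      poolSize <- min(cfg$tendency$background_pool_size, length(bgTx))
      set.seed(.stageSeed(cfg$seed, "tendency"))
      bgPool <- sample(bgTx, poolSize)
      k <- cfg$tendency$k
      if (is.null(k)) k <- max(2L, floor(0.7 * length(reps)))
      prof <- tendencyProfile(expr, reps, bgPool, k = k,
                              pGrid = cfg$tendency$p_grid,
                              replications = cfg$tendency$replications,
                              seed = .stageSeed(cfg$seed, "tendency"),
                              method = cfg$correlation$method,
                              logTransform = cfg$correlation$log_transform)
      folds <- connectivityFold(expr, reps, bgPool, k = k,
                                cutoffs = cfg$tendency$connectivity_cutoffs,
                                replications = cfg$tendency$replications,
                                seed = .stageSeed(cfg$seed, "tendency"),
                                method = cfg$correlation$method,
                                logTransform = cfg$correlation$log_transform)
      emit(function(x, f) utils::write.table(x, f, sep = "\t", quote = FALSE,
                                             row.names = FALSE),
           tendencyTable(prof), "tendency.tsv")
      list(k = k, profile = tendencyTable(prof), tests = tendencyTests(prof),
           connectivity_folds = folds)
    })
  }

  # ---- phenotype groups ----
  if ("groups" %in% stages && !all(is.na(pheno))) {
    report$groups <- .runStage("groups", {
      gsize <- cfg$groups$group_size
      if (is.null(gsize)) gsize <- floor(length(pheno) / cfg$groups$n_groups)
      part <- partitionPhenotype(pheno, cfg$groups$n_groups, gsize)
      rep_ <- groupConsistency(expr, part, candidates = reps,
                               pCutoff = cfg$groups$p_cutoff,
                               alpha = cfg$groups$alpha,
                               method = cfg$groups$consistency,
                               pheno = pheno,
                               logTransform = cfg$correlation$log_transform)
      if (!is.null(outDir))
        for (g in names(rep_@networks))
          writeNetwork(rep_@networks[[g]],
                       file.path(outDir, paste0("network_", g, ".tsv")))
      pd <- rep_@percentDiffs
      list(partition = part@stats, dropped = part@dropped,
           group_networks = rep_@groupSummaries,
           node_consistency_pct = rep_@nodeConsistency,
           edge_consistency_pct = rep_@edgeConsistency,
           anova = rep_@anova[c("F", "df_between", "df_within", "p",
                                "letters", "exact_separation")],
           percent_diff_range = c(attr(pd, "range_min"),
                                  attr(pd, "range_max")))
    })
  }

  report$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  if (!is.null(outDir))
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         pretty = TRUE)
  invisible(report)
}
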