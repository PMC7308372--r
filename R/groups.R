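#' Partition a genotype panel into equal-size phenotype groups
#'
#' Sorts samples by ascending phenotype (ties broken by sample ID), drops
#' any excess samples symmetrically from around the overall median rank,
#' and splits the remainder into \code{nGroups} contiguous groups of
#' \code{groupSize}. Groups are therefore ordered G1 (lowest phenotype) to
#' Gn (highest). A subset of groups (e.g. the extremes plus the middle) can
#' be extracted with \code{selectedGroups}.
#'
#' @param pheno named numeric, phenotype per sample.
#' @param nGroups number of groups.
#' @param groupSize samples per group.
#' @param selectedGroups indices of groups to keep (default all).
#' @return a \linkS4class{GroupPartition}.
#' @examples
#' ph <- stats::setNames(1:9, paste0("s", 1:9))
#' phenotypeGroups(partitionPhenotype(ph, 3, 3))
#' @export
partitionPhenotype <- function(pheno, nGroups, groupSize,
                               selectedGroups = seq_len(nGroups)) {
  stopifnot(nGroups >= 1L, groupSize >= 1L)
  n <- length(pheno)
  need <- nGroups * groupSize
  if (need > n)
    stop("insufficient samples: need ", need, ", have ", n)
  ord <- order(pheno, names(pheno))
  ids <- names(pheno)[ord]
  excess <- n - need
  dropped <- character()
  if (excess > 0L) {
    center <- (n + 1) / 2
    byMid <- order(abs(seq_len(n) - center), seq_len(n))
    dropIdx <- sort(byMid[seq_len(excess)])
    dropped <- ids[dropIdx]
    ids <- ids[-dropIdx]
  }
  groups <- split(ids, rep(seq_len(nGroups), each = groupSize))
  names(groups) <- paste0("G", seq_len(nGroups))
  groups <- groups[selectedGroups]
  stats <- data.frame(
    group = names(groups),
    n = lengths(groups),
    mean = vapply(groups, function(g) mean(pheno[g]), 0),
    sd = vapply(groups, function(g) stats::sd(pheno[g]), 0),
    stringsAsFactors = FALSE)
  rownames(stats) <- NULL
  new("GroupPartition", groups = groups, stats = stats,
      dropped = dropped, phenotype = pheno[unlist(groups, use.names = FALSE)])
}

#' One-way ANOVA with Fisher's LSD separation of group phenotypes
#'
#' Fixed-effects one-way ANOVA across the phenotype groups followed by
#' Fisher's least-significant-difference pairwise comparisons using the
#' pooled within-group variance, summarized as a compact letter display
#' assigned ascending by group mean (groups sharing a letter do not differ
#' at \code{alpha}). By default the LSD comparisons are unprotected
#' (performed regardless of the overall F); \code{protected = TRUE} gives
#' every group the same letter when the overall F is not significant.
#'
#' @param groups named list of numeric vectors (>= 2 groups, >= 2 values
#'   each), or a \linkS4class{GroupPartition} plus \code{pheno}.
#' @param pheno named phenotype vector, required when \code{groups} is a
#'   \linkS4class{GroupPartition}.
#' @param alpha significance level for the LSD comparisons (default 0.01).
#' @param protected require overall F significance before separating.
#' @return list(F, df_between, df_within, p, letters, means,
#'   exact_separation). With zero within-group variance everywhere the
#'   design is exactly separated: F is infinite and p is reported as 0 by
#'   convention, with \code{exact_separation = TRUE}.
#' @export
anovaLsd <- function(groups, pheno = NULL, alpha = 0.01, protected = FALSE) {
  if (is(groups, "GroupPartition")) {
    if (is.null(pheno)) pheno <- groups@phenotype
    groups <- lapply(groups@groups, function(ids) unname(pheno[ids]))
  }
  k <- length(groups)
  stopifnot(k >= 2L, all(lengths(groups) >= 2L))
  if (is.null(names(groups))) names(groups) <- paste0("G", seq_len(k))
  ns <- lengths(groups)
  means <- vapply(groups, mean, 0)
  grand <- sum(unlist(groups)) / sum(ns)
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  dfb <- k - 1L
  dfw <- sum(ns) - k
  if (ssw == 0) {
    allEqual <- isTRUE(all.equal(max(means), min(means)))
    sep <- !allEqual
    lets <- if (allEqual) rep("a", k)
            else letters[match(means, sort(unique(means)))]
    return(list(F = if (sep) Inf else 0, df_between = dfb, df_within = dfw,
                p = if (sep) 0 else 1,
                letters = stats::setNames(lets, names(groups)),
                means = means, exact_separation = sep))
  }
  msb <- ssb / dfb
  msw <- ssw / dfw
  Fval <- msb / msw
  p <- stats::pf(Fval, dfb, dfw, lower.tail = FALSE)

  # pairwise LSD: |mi - mj| > t_{1-alpha/2, dfw} * sqrt(msw (1/ni + 1/nj))
  tcrit <- stats::qt(1 - alpha / 2, dfw)
  ordIdx <- order(means)
  differs <- matrix(FALSE, k, k)
  for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
    lsd <- tcrit * sqrt(msw * (1 / ns[i] + 1 / ns[j]))
    differs[i, j] <- differs[j, i] <- abs(means[i] - means[j]) > lsd
  }
  if (protected && p > alpha) differs[] <- FALSE
  cld <- .compactLetters(differs[ordIdx, ordIdx, drop = FALSE])
  lets <- character(k)
  lets[ordIdx] <- cld
  list(F = Fval, df_between = dfb, df_within = dfw, p = p,
       letters = stats::setNames(lets, names(groups)),
       means = means, exact_separation = FALSE)
}

# insert-and-absorb compact letter display; groups are pre-sorted by mean,
# differs[i, j] TRUE when groups i and j are significantly different.
# Start from one set of all groups; each significant pair splits every set
# containing both members; subset sets are absorbed.
.compactLetters <- function(differs) {
  k <- nrow(differs)
  sets <- list(seq_len(k))
  for (i in seq_len(max(k - 1L, 0L))) for (j in seq(i + 1L, k)) {
    if (j > k || !differs[i, j]) next
    newSets <- list()
    for (s in sets) {
      if (i %in% s && j %in% s)
        newSets <- c(newSets, list(setdiff(s, i)), list(setdiff(s, j)))
      else newSets <- c(newSets, list(s))
    }
    newSets <- unique(lapply(newSets, sort))
    keep <- vapply(seq_along(newSets), function(a)
      !any(vapply(seq_along(newSets), function(b)
        a != b && all(newSets[[a]] %in% newSets[[b]]) &&
          length(newSets[[a]]) < length(newSets[[b]]), TRUE)), TRUE)
    sets <- newSets[keep]
  }
  ord <- order(vapply(sets, min, 0L))
  sets <- sets[ord]
  out <- character(k)
  for (s in seq_along(sets))
    for (g in sets[[s]]) out[g] <- paste0(out[g], letters[s])
  out
}

#' Pairwise percent differences between group means
#'
#' For each pair of groups, 100 * (larger - smaller) / smaller; the min-max
#' range across pairs summarizes how far the groups are separated on the
#' trait scale.
#'
#' @param means named numeric vector of positive group means.
#' @return data.frame of pairs with percent differences; attributes
#'   \code{range_min}/\code{range_max} hold the summary range.
#' @export
percentDifferences <- function(means) {
  if (any(means <= 0)) stop("group means must be positive on the trait scale")
  k <- length(means)
  if (is.null(names(means))) names(means) <- paste0("G", seq_len(k))
  stopifnot(k >= 2L)
  pairs <- utils::combn(k, 2)
  pct <- apply(pairs, 2L, function(ij) {
    a <- means[ij[1]]; b <- means[ij[2]]
    100 * (max(a, b) - min(a, b)) / min(a, b)
  })
  out <- data.frame(group_a = names(means)[pairs[1, ]],
                    group_b = names(means)[pairs[2, ]],
                    percent_diff = as.numeric(pct),
                    stringsAsFactors = FALSE)
  attr(out, "range_min") <- min(pct)
  attr(out, "range_max") <- max(pct)
  out
}

#' Node and edge consistency of networks across phenotype groups
#'
#' Consistency is the intersection-over-union percentage across all group
#' networks, computed separately for non-isolated node sets and for edge
#' sets (edges matched as unordered ID pairs, ignoring r and p). The
#' alternative convention \code{method = "candidate"} divides the size of
#' the everywhere-present set by the candidate-set size instead. An empty
#' union (no structure in any group) is defined as 100 with a flag.
#'
#' @param networks list of >= 2 \linkS4class{CoexpressionNetwork} built
#'   over the same candidate set.
#' @param method "iou" (default) or "candidate".
#' @return list(node_consistency_pct, edge_consistency_pct, empty_union).
#' @export
networkConsistency <- function(networks, method = c("iou", "candidate")) {
  method <- match.arg(method)
  stopifnot(length(networks) >= 2L)
  cand <- candidateSet(networks[[1]])
  for (nw in networks[-1])
    if (!setequal(candidateSet(nw), cand))
      stop("all networks must share the same candidate transcript set")
  nodeSets <- lapply(networks, networkNodes)
  edgeSets <- lapply(networks, function(nw) {
    e <- networkEdges(nw)
    paste(e$node_a, e$node_b, sep = "|")
  })
  pct <- function(sets, denomCandidate = NULL) {
    inter <- Reduce(intersect, sets)
    uni <- Reduce(union, sets)
    if (length(uni) == 0L) return(list(pct = 100, empty = TRUE))
    denom <- if (is.null(denomCandidate)) length(uni)
             else length(denomCandidate)
    list(pct = 100 * length(inter) / denom, empty = FALSE)
  }
  if (method == "iou") {
    nodeRes <- pct(nodeSets)
    edgeRes <- pct(edgeSets)
  } else {
    nodeRes <- pct(nodeSets, denomCandidate = cand)
    allPairs <- utils::combn(sort(cand), 2)
    edgeRes <- pct(edgeSets,
                   denomCandidate = paste(allPairs[1, ], allPairs[2, ],
                                          sep = "|"))
  }
  list(node_consistency_pct = nodeRes$pct,
       edge_consistency_pct = edgeRes$pct,
       empty_union = nodeRes$empty && edgeRes$empty)
}

#' Per-group networks and their cross-group consistency
#'
#' Builds one co-expression network per phenotype group (at P <= 0.01 by
#' default, the convention for group-wise comparison), verifies the group
#' separation with one-way ANOVA + LSD and pairwise percent differences,
#' and reports node/edge consistency across the group networks.
#'
#' @param x \linkS4class{TraitExperiment} or abundance matrix.
#' @param partition a \linkS4class{GroupPartition}.
#' @param candidates transcript IDs for the per-group networks.
#' @param pCutoff per-group network cutoff (default 0.01).
#' @param alpha LSD significance level (default 0.01).
#' @param method consistency convention, "iou" or "candidate".
#' @param pheno phenotype vector, needed when \code{x} is a bare matrix.
#' @param ... further arguments to \code{\link{buildNetwork}}.
#' @return a \linkS4class{ConsistencyReport}.
#' @export
groupConsistency <- function(x, partition, candidates, pCutoff = 0.01,
                             alpha = 0.01, method = "iou", pheno = NULL,
                             ...) {
  if (is(x, "TraitExperiment")) {
    if (is.null(pheno)) pheno <- phenotype(x)
    x <- abundance(x)
  }
  groups <- phenotypeGroups(partition)
  networks <- lapply(groups, function(ids)
    buildNetwork(x[, ids, drop = FALSE], candidates = candidates,
                 pCutoff = pCutoff, ...))
  cons <- networkConsistency(networks, method = method)
  an <- anovaLsd(lapply(groups, function(ids) unname(pheno[ids])),
                 alpha = alpha)
  pd <- percentDifferences(vapply(groups, function(ids) mean(pheno[ids]), 0))
  gs <- data.frame(
    group = names(groups),
    n_nodes = vapply(networks, function(nw) length(networkNodes(nw)), 0L),
    n_edges = vapply(networks, function(nw) nrow(networkEdges(nw)), 0L),
    stringsAsFactors = FALSE)
  rownames(gs) <- NULL
  new("ConsistencyReport",
      groupSummaries = gs,
      nodeConsistency = cons$node_consistency_pct,
      edgeConsistency = cons$edge_consistency_pct,
      anova = an, percentDiffs = pd, networks = networks,
      method = method)
}
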