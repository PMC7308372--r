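#' Default p-value grid for tendency profiles
#'
#' Eight cutoffs from 5e-2 down to 1e-8, the span over which the
#' network-formation tendency is profiled.
#' @export
defaultPGrid <- function() c(5e-2, 1e-2, 1e-3, 1e-4, 1e-5, 1e-6, 1e-7, 1e-8)

#' Bootstrap-sample fixed-size transcript subsets
#'
#' Draws \code{replications} subsets of \code{k} distinct transcripts,
#' uniformly and independently across replicates (sets may repeat between
#' replicates; within a replicate transcripts are not repeated, since a
#' network over a fixed-size set requires distinct members).
#'
#' @param pool character vector of transcript IDs.
#' @param k subset size.
#' @param replications number of subsets (default 100).
#' @param seed RNG seed.
#' @return list of character vectors, each of length k.
#' @export
sampleSets <- function(pool, k, replications = 100L, seed = 1L) {
  if (k > length(pool))
    stop("k (", k, ") exceeds pool size (", length(pool), ")")
  set.seed(as.integer(seed))
  lapply(seq_len(replications), function(i) sample(pool, k))
}

# per-replicate node/edge counts (and optionally vertex connectivity) at
# every cutoff, reusing one correlation pass per replicate so profiles are
# non-increasing along the grid within a replicate by construction
.tendencyCounts <- function(exprLog, sets, pGrid, method = "pearson",
                            connectivity = FALSE) {
  nC <- length(pGrid); nR <- length(sets)
  nodes <- matrix(0L, nC, nR); edges <- matrix(0L, nC, nR)
  conn <- if (connectivity) matrix(0L, nC, nR) else NULL
  for (j in seq_len(nR)) {
    m <- exprLog[sets[[j]], , drop = FALSE]
    cp <- .corPairs(m, method)
    ut <- which(upper.tri(cp$p), arr.ind = TRUE)
    pv <- cp$p[ut]
    ok <- !is.na(pv)
    for (i in seq_len(nC)) {
      sel <- ok & pv <= pGrid[i]
      edges[i, j] <- sum(sel)
      ends <- unique(c(ut[sel, 1L], ut[sel, 2L]))
      nodes[i, j] <- length(ends)
      if (connectivity) {
        conn[i, j] <- if (length(ends) < 2L) 0L else {
          g <- igraph::graph_from_edgelist(
            cbind(ut[sel, 1L], ut[sel, 2L]), directed = FALSE)
          g <- igraph::induced_subgraph(
            igraph::simplify(g), which(igraph::degree(g) > 0))
          as.integer(igraph::vertex_connectivity(g))
        }
      }
    }
  }
  list(nodes = nodes, edges = edges, connectivity = conn)
}

# two-sample Student's t with explicit handling of zero pooled variance:
# identical constant arms give t undefined -> p = 1 (degenerate flag);
# separated constant arms give exact separation -> p = 0
.twoSampleT <- function(a, b, varEqual = TRUE) {
  na <- length(a); nb <- length(b)
  ma <- mean(a); mb <- mean(b)
  va <- stats::var(a); vb <- stats::var(b)
  if (varEqual) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    if (!is.finite(df)) df <- na + nb - 2
  }
  if (!is.finite(se) || se == 0) {
    if (isTRUE(all.equal(ma, mb)))
      return(list(t = NA_real_, p = 1, degenerate = TRUE))
    return(list(t = sign(ma - mb) * Inf, p = 0, degenerate = TRUE))
  }
  tval <- (ma - mb) / se
  list(t = tval, p = 2 * stats::pt(abs(tval), df, lower.tail = FALSE),
       degenerate = FALSE)
}

#' Network-formation tendency of a trait set versus a bootstrap null
#'
#' For each cutoff of a decreasing p-value grid, builds co-expression
#' networks for \code{replications} bootstrap subsets of size k drawn from
#' the trait-transcript pool and for the same number of subsets from the
#' random background pool, records node (edge-participating) and edge
#' counts per replicate, and compares the two arms with a two-tailed
#' Student's t-test (equal-variance by default; Welch via
#' \code{varEqual = FALSE}). Both arms are subsampled at the same k;
#' \code{fixedTrait = TRUE} instead keeps the full trait pool fixed in the
#' trait arm and only resamples the random arm.
#'
#' @param x \linkS4class{TraitExperiment} or abundance matrix.
#' @param traitPool,backgroundPool disjoint transcript ID vectors.
#' @param k subset size per replicate (defaults to \code{length(traitPool)}
#'   when \code{fixedTrait}).
#' @param pGrid strictly decreasing cutoffs (default
#'   \code{\link{defaultPGrid}()}).
#' @param replications bootstrap replications per arm (default 100).
#' @param seed RNG seed.
#' @param method,logTransform correlation settings.
#' @param varEqual equal-variance t-test (default) or Welch.
#' @param fixedTrait keep the trait arm fixed at the full pool.
#' @return a \linkS4class{NullTendencyProfile}.
#' @export
tendencyProfile <- function(x, traitPool, backgroundPool, k,
                            pGrid = defaultPGrid(), replications = 100L,
                            seed = 1L, method = "pearson",
                            logTransform = TRUE, varEqual = TRUE,
                            fixedTrait = FALSE) {
  if (is(x, "TraitExperiment")) x <- abundance(x)
  if (length(intersect(traitPool, backgroundPool)))
    stop("trait and background pools must be disjoint")
  if (missing(k)) k <- length(traitPool)
  if (k > length(backgroundPool))
    stop("background pool (", length(backgroundPool),
         ") is smaller than k (", k, ")")
  if (!fixedTrait && k > length(traitPool))
    stop("trait pool (", length(traitPool), ") is smaller than k (", k, ")")
  if (any(diff(pGrid) >= 0)) stop("pGrid must be strictly decreasing")
  replications <- as.integer(replications)
  if (replications < 2L) stop("replications must be >= 2")

  m <- x[c(traitPool, backgroundPool), , drop = FALSE]
  if (logTransform) m <- log2(m + 1)
  traitSets <- if (fixedTrait)
    rep(list(traitPool), replications)
  else sampleSets(traitPool, k, replications, seed)
  bgSets <- sampleSets(backgroundPool, k, replications,
                       seed = as.integer(seed) + 1L)

  tc <- .tendencyCounts(m, traitSets, pGrid, method)
  bc <- .tendencyCounts(m, bgSets, pGrid, method)

  rows <- list(); tests <- list()
  for (i in seq_along(pGrid)) {
    for (meas in c("nodes", "edges")) {
      tvals <- tc[[meas]][i, ]; bvals <- bc[[meas]][i, ]
      rows[[length(rows) + 1L]] <- data.frame(
        cutoff = pGrid[i], measure = meas,
        arm = c("trait", "random"),
        mean = c(mean(tvals), mean(bvals)),
        sd = c(stats::sd(tvals), stats::sd(bvals)),
        n = replications, stringsAsFactors = FALSE)
      tt <- .twoSampleT(tvals, bvals, varEqual)
      tests[[length(tests) + 1L]] <- data.frame(
        cutoff = pGrid[i], measure = meas, t = tt$t, p = tt$p,
        degenerate = tt$degenerate, stringsAsFactors = FALSE)
    }
  }
  new("NullTendencyProfile",
      profile = do.call(rbind, rows), tests = do.call(rbind, tests),
      replicates = list(trait = tc[c("nodes", "edges")],
                        random = bc[c("nodes", "edges")]),
      pGrid = pGrid, replications = replications, k = as.integer(k),
      seed = as.integer(seed))
}

#' Connectivity fold of trait networks over random networks
#'
#' At each cutoff, the mean vertex connectivity over bootstrap trait-subset
#' networks divided by the mean over random-subset networks. When the
#' random-arm mean is zero the fold is reported as \code{Inf} with both
#' means preserved.
#'
#' @inheritParams tendencyProfile
#' @param cutoffs p-value cutoffs (default 0.05, 0.01, 0.001).
#' @return data.frame: cutoff, trait_mean, random_mean, fold.
#' @export
connectivityFold <- function(x, traitPool, backgroundPool, k,
                             cutoffs = c(0.05, 0.01, 0.001),
                             replications = 100L, seed = 1L,
                             method = "pearson", logTransform = TRUE,
                             fixedTrait = FALSE) {
  if (is(x, "TraitExperiment")) x <- abundance(x)
  if (length(intersect(traitPool, backgroundPool)))
    stop("trait and background pools must be disjoint")
  if (missing(k)) k <- length(traitPool)
  if (k > length(backgroundPool))
    stop("background pool (", length(backgroundPool),
         ") is smaller than k (", k, ")")
  if (!fixedTrait && k > length(traitPool))
    stop("trait pool (", length(traitPool), ") is smaller than k (", k, ")")
  cutoffs <- sort(cutoffs, decreasing = TRUE)
  m <- x[c(traitPool, backgroundPool), , drop = FALSE]
  if (logTransform) m <- log2(m + 1)
  traitSets <- if (fixedTrait)
    rep(list(traitPool), replications)
  else sampleSets(traitPool, k, replications, seed)
  bgSets <- sampleSets(backgroundPool, k, replications,
                       seed = as.integer(seed) + 1L)
  tc <- .tendencyCounts(m, traitSets, cutoffs, method, connectivity = TRUE)
  bc <- .tendencyCounts(m, bgSets, cutoffs, method, connectivity = TRUE)
  tm <- rowMeans(tc$connectivity); bm <- rowMeans(bc$connectivity)
  data.frame(cutoff = cutoffs, trait_mean = tm, random_mean = bm,
             fold = ifelse(bm == 0, Inf, tm / bm))
}
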