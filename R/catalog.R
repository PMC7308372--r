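#' Filter tabular homology hits by the published-gene criteria
#'
#' Retains exactly the hits with alignment length >= \code{minAlignLen},
#' percent identity >= \code{minIdentity} and E-value <= \code{maxEvalue};
#' boundary values are retained. The alignment-length column stands in for
#' query cover in bases, since percent cover is not computable without the
#' query lengths; supply \code{queryLengths} to switch to a percent-cover
#' threshold instead (\code{minCoverPct} of the query length).
#'
#' @param hits data.frame with at least qseqid, sseqid, pident, length,
#'   evalue (e.g. from \code{\link{readBlastTable}}).
#' @param minAlignLen minimum alignment length in bases (default 300).
#' @param minIdentity minimum percent identity (default 90).
#' @param maxEvalue maximum E-value (default 1e-6).
#' @param queryLengths optional named numeric of query sequence lengths;
#'   when given, the coverage criterion becomes
#'   \code{length / queryLengths[qseqid] * 100 >= minCoverPct}.
#' @param minCoverPct percent-cover threshold used with \code{queryLengths}.
#' @return the retained rows of \code{hits}. Filtering is idempotent.
#' @export
filterHits <- function(hits, minAlignLen = 300, minIdentity = 90,
                       maxEvalue = 1e-6, queryLengths = NULL,
                       minCoverPct = 50) {
  stopifnot(minAlignLen > 0, minIdentity > 0, maxEvalue > 0)
  need <- c("qseqid", "sseqid", "pident", "length", "evalue")
  if (!all(need %in% names(hits)))
    stop("hits must have columns ", paste(need, collapse = ", "))
  for (col in c("pident", "length", "evalue")) {
    bad <- which(!is.finite(hits[[col]]))
    if (length(bad))
      stop("non-numeric or missing '", col, "' at row ", bad[1])
  }
  if (any(hits$pident < 0 | hits$pident > 100))
    stop("pident must be in [0, 100]")
  covOk <- if (is.null(queryLengths)) {
    hits$length >= minAlignLen
  } else {
    ql <- queryLengths[hits$qseqid]
    if (any(is.na(ql))) stop("queryLengths missing for some qseqid")
    hits$length / ql * 100 >= minCoverPct
  }
  hits[covOk & hits$pident >= minIdentity & hits$evalue <= maxEvalue, ,
       drop = FALSE]
}

#' Build a gene-to-transcript map from filtered hits
#'
#' One entry per unique (gene, transcript) pair; when several hits link the
#' same pair, the maximum identity is kept. Transcripts are ordered within
#' gene by decreasing identity then lexicographic transcript ID.
#'
#' @param hits filtered hit table (see \code{\link{filterHits}}).
#' @return data.frame with columns gene_id, transcript_id, identity_pct.
#' @export
buildGeneMap <- function(hits) {
  if (nrow(hits) == 0L)
    return(data.frame(gene_id = character(), transcript_id = character(),
                      identity_pct = numeric(), stringsAsFactors = FALSE))
  key <- paste(hits$qseqid, hits$sseqid, sep = "\r")
  best <- tapply(hits$pident, key, max)
  parts <- strsplit(names(best), "\r", fixed = TRUE)
  map <- data.frame(gene_id = vapply(parts, `[`, "", 1L),
                    transcript_id = vapply(parts, `[`, "", 2L),
                    identity_pct = as.numeric(best),
                    stringsAsFactors = FALSE)
  map <- map[order(map$gene_id, -map$identity_pct, map$transcript_id), ]
  rownames(map) <- NULL
  map
}

#' Per-gene transcript-count summary
#'
#' Counts transcripts per gene and summarizes the alternative-splicing
#' structure of the catalog: how many genes are multi-transcript (>= 2
#' transcripts, i.e. alternatively spliced), how many are single-transcript,
#' the count range and the mean transcripts per gene (reported to 1
#' decimal, as conventional).
#'
#' @param map gene map data.frame (gene_id, transcript_id, ...), or a named
#'   integer vector of per-gene counts.
#' @return list with \code{counts} (named per-gene), \code{n_genes},
#'   \code{n_multi}, \code{n_single}, \code{min}, \code{max}, \code{mean}.
#' @export
transcriptCountSummary <- function(map) {
  counts <- if (is.data.frame(map)) {
    if (nrow(map) == 0L) stop("empty gene map")
    table(map$gene_id)
  } else {
    if (length(map) == 0L) stop("empty gene map")
    map
  }
  counts <- stats::setNames(as.integer(counts), names(counts))
  list(counts = counts,
       n_genes = length(counts),
       n_multi = sum(counts >= 2L),
       n_single = sum(counts == 1L),
       min = min(counts), max = max(counts),
       mean = round(sum(counts) / length(counts), 1))
}

#' Select representative transcripts per gene
#'
#' Per gene, picks the transcript with the highest identity to the
#' published cDNA; a second transcript is added when its identity lies
#' within \code{tieWindow} percentage points of the best (the "very close
#' identities" situation) and \code{maxPerGene} is 2. Ties break
#' lexicographically by transcript ID, so selection is deterministic.
#'
#' @param map gene map with identity_pct per (gene, transcript).
#' @param maxPerGene 1 or 2 representatives per gene.
#' @param tieWindow identity window (percentage points) for the second
#'   representative.
#' @return character vector of representative transcript IDs; the gene of
#'   each is available as names.
#' @export
selectRepresentatives <- function(map, maxPerGene = 2L, tieWindow = 0.5) {
  stopifnot(maxPerGene %in% 1:2, tieWindow >= 0)
  genes <- unique(map$gene_id)
  out <- character(); gene_of <- character()
  for (g in genes) {
    sub <- map[map$gene_id == g, , drop = FALSE]
    if (nrow(sub) == 0L) { warning("gene ", g, " has no transcripts; skipped"); next }
    sub <- sub[order(-sub$identity_pct, sub$transcript_id), , drop = FALSE]
    pick <- sub$transcript_id[1L]
    if (maxPerGene == 2L && nrow(sub) >= 2L &&
        sub$identity_pct[1L] - sub$identity_pct[2L] <= tieWindow)
      pick <- c(pick, sub$transcript_id[2L])
    out <- c(out, pick)
    gene_of <- c(gene_of, rep(g, length(pick)))
  }
  stats::setNames(out, gene_of)
}
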