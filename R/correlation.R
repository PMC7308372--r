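# Shared correlation machinery: r and the two-tailed p from
# t = r * sqrt(n-2) / sqrt(1-r^2), df = n-2 (the cor.test formula),
# vectorized over all row pairs of a matrix. Spearman replaces values by
# ranks first (t approximation, as in cor.test(exact = FALSE)).
.corPairs <- function(mat, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  n <- ncol(mat)
  if (method == "spearman") mat <- t(apply(mat, 1L, rank))
  r <- suppressWarnings(stats::cor(t(mat)))
  r[r > 1] <- 1; r[r < -1] <- -1
  tval <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, 0))
  p <- 2 * stats::pt(abs(tval), df = n - 2, lower.tail = FALSE)
  p[!is.finite(tval)] <- 0  # |r| = 1 exactly
  p[is.na(r)] <- NA_real_   # zero-variance rows
  list(r = r, p = p, n = n)
}

.corVec <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  n <- length(y)
  if (method == "spearman") { x <- t(apply(x, 1L, rank)); y <- rank(y) }
  r <- suppressWarnings(as.numeric(stats::cor(t(x), y)))
  r[r > 1] <- 1; r[r < -1] <- -1
  tval <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, 0))
  p <- 2 * stats::pt(abs(tval), df = n - 2, lower.tail = FALSE)
  p[is.finite(r) & !is.finite(tval)] <- 0
  p[is.na(r)] <- NA_real_
  data.frame(r = r, p = p)
}

#' Correlate every transcript's expression with the trait phenotype
#'
#' Screens each transcript for significant correlation between its
#' expression across lines and the trait value, on the samples shared
#' between the two inputs. Expression is log2(x + 1)-transformed by default
#' before computing the coefficient; the two-tailed p comes from the
#' t-distribution of r (Pearson) or its rank analogue (Spearman).
#' Transcripts with zero expression variance are reported with r = NA and
#' never flagged significant.
#'
#' @param x a \linkS4class{TraitExperiment}, or an abundance matrix
#'   (transcripts x samples) when \code{pheno} is given.
#' @param pheno named numeric phenotype per sample (ignored for a
#'   \linkS4class{TraitExperiment}).
#' @param method "pearson" (default) or "spearman".
#' @param logTransform apply log2(x + 1) before correlating.
#' @param alpha two-tailed significance level for the \code{significant}
#'   flag (default 0.05, uncorrected, as in a raw correlation screen).
#' @param adjust optional p-adjustment method (e.g. "BH") applied before
#'   flagging; "none" keeps the raw screen.
#' @return data.frame: transcript_id, r, p, n, significant.
#' @export
correlateTrait <- function(x, pheno = NULL, method = "pearson",
                           logTransform = TRUE, alpha = 0.05,
                           adjust = "none") {
  if (is(x, "TraitExperiment")) {
    pheno <- phenotype(x)
    x <- abundance(x)
  }
  if (is.null(names(pheno)) || is.null(colnames(x)))
    stop("expression columns and phenotype entries must both be named by sample ID")
  shared <- intersect(colnames(x), names(pheno))
  if (length(shared) < 4L) {
    missing <- setdiff(names(pheno), colnames(x))
    stop("need >= 4 shared samples between expression and phenotype; ",
         length(shared), " found",
         if (length(missing)) paste0(" (phenotype samples absent from ",
                                     "expression: ",
                                     paste(utils::head(missing, 5), collapse = ", "), ")"))
  }
  y <- pheno[shared]
  if (any(!is.finite(y))) stop("phenotype values must be finite")
  m <- x[, shared, drop = FALSE]
  if (logTransform) m <- log2(m + 1)
  res <- .corVec(m, y, method)
  padj <- if (identical(adjust, "none")) res$p
          else stats::p.adjust(res$p, method = adjust)
  out <- data.frame(transcript_id = rownames(x), r = res$r, p = res$p,
                    n = length(shared),
                    significant = !is.na(res$r) & !is.na(padj) & padj <= alpha,
                    stringsAsFactors = FALSE)
  attr(out, "method") <- method
  attr(out, "logTransform") <- logTransform
  attr(out, "alpha") <- alpha
  attr(out, "adjust") <- adjust
  out
}

#' Per-gene summary of the transcript-phenotype correlation screen
#'
#' Aggregates the transcript screen by gene: how many of each gene's
#' transcripts are significantly correlated with the phenotype, the mean
#' number of significant transcripts per gene (1 decimal), the pooled
#' fraction significant, and the genes with no significant transcript.
#'
#' @param results data.frame from \code{\link{correlateTrait}}.
#' @param map gene map covering every transcript in \code{results}.
#' @return list(per_gene, mean_significant, pooled_fraction,
#'   genes_without_significant).
#' @export
perGeneSummary <- function(results, map) {
  gene <- map$gene_id[match(results$transcript_id, map$transcript_id)]
  if (any(is.na(gene)))
    stop("unmapped transcripts: ",
         paste(utils::head(results$transcript_id[is.na(gene)], 5),
               collapse = ", "))
  perGene <- data.frame(
    gene_id = sort(unique(gene)),
    stringsAsFactors = FALSE)
  sig <- tapply(results$significant, gene, sum)
  tot <- tapply(results$significant, gene, length)
  perGene$n_significant <- as.integer(sig[perGene$gene_id])
  perGene$total_transcripts <- as.integer(tot[perGene$gene_id])
  rownames(perGene) <- NULL
  list(per_gene = perGene,
       mean_significant = round(mean(perGene$n_significant), 1),
       pooled_fraction = sum(perGene$n_significant) /
                         sum(perGene$total_transcripts),
       genes_without_significant =
         perGene$gene_id[perGene$n_significant == 0L])
}
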