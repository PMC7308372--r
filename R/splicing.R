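#' Background fractions of multi- vs single-transcript genes
#'
#' Computes, over all genes expressed in the tissue, the fractions of genes
#' alternatively spliced into two or more transcripts and of genes with a
#' single transcript. These background fractions set the expected counts
#' for \code{\link{enrichmentTest}}.
#'
#' @param geneCounts named integer vector of transcripts per gene (>= 1),
#'   or a gene map data.frame.
#' @return list(bg_multi_frac, bg_single_frac, n_genes).
#' @export
backgroundFractions <- function(geneCounts) {
  if (is.data.frame(geneCounts)) geneCounts <- table(geneCounts$gene_id)
  geneCounts <- as.integer(geneCounts)
  if (length(geneCounts) == 0L) stop("empty background gene set")
  if (any(geneCounts < 1L)) stop("every gene must have >= 1 transcript")
  multi <- mean(geneCounts >= 2L)
  list(bg_multi_frac = multi, bg_single_frac = 1 - multi,
       n_genes = length(geneCounts))
}

#' Chi-square enrichment test for alternative splicing of trait genes
#'
#' Tests whether the genes controlling the trait are enriched for the
#' multi-transcript (alternatively spliced) state relative to the organ-wide
#' background. Expected counts are the trait-set size times the background
#' fractions; the statistic is the plain two-cell goodness-of-fit chi-square
#' with 1 degree of freedom (no continuity correction by default, matching
#' the plain chi-square test; enable \code{correct} for Yates' correction,
#' which is material for the small trait sets typical here, n = 8--26).
#'
#' @param traitMulti count of trait genes with >= 2 transcripts.
#' @param traitSingle count of trait genes with a single transcript.
#' @param bgMultiFrac background fraction of multi-transcript genes, in (0,1).
#' @param alpha significance level for the direction call (default 0.01).
#' @param correct apply Yates' continuity correction.
#' @return list(observed, expected, chi2, df = 1, p, direction) where
#'   direction is "up" when multi-transcript genes exceed expectation at
#'   significance, "down" when they fall short, "none" otherwise.
#' @examples
#' enrichmentTest(9, 1, 0.5)   # chi2 = 6.4, p ~ 0.0114, up
#' @export
enrichmentTest <- function(traitMulti, traitSingle, bgMultiFrac,
                           alpha = 0.01, correct = FALSE) {
  stopifnot(traitMulti >= 0, traitSingle >= 0,
            traitMulti + traitSingle >= 1)
  if (!is.finite(bgMultiFrac) || bgMultiFrac <= 0 || bgMultiFrac >= 1)
    stop("degenerate background: bgMultiFrac must be strictly inside (0,1)")
  n <- traitMulti + traitSingle
  expMulti <- n * bgMultiFrac
  expSingle <- n * (1 - bgMultiFrac)
  dev <- abs(c(traitMulti, traitSingle) - c(expMulti, expSingle))
  if (correct) dev <- pmax(dev - 0.5, 0)
  chi2 <- sum(dev^2 / c(expMulti, expSingle))
  p <- stats::pchisq(chi2, df = 1L, lower.tail = FALSE)
  direction <- if (p <= alpha) {
    if (traitMulti > expMulti) "up" else if (traitMulti < expMulti) "down"
    else "none"
  } else "none"
  list(observed = c(multi = traitMulti, single = traitSingle),
       expected = c(multi = expMulti, single = expSingle),
       chi2 = chi2, df = 1L, p = p, direction = direction)
}
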