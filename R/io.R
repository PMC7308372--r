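# Strict TSV dialects. All writers emit plain tab-separated text with full
# double precision (15 significant digits), so write -> read round trips
# are lossless well past 12 significant digits.

.checkNumericCols <- function(df, cols, path) {
  for (col in cols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) & df[[col]] != "NA")
    if (length(bad))
      stop("non-numeric value in column '", col, "' of ", path,
           " at data row ", bad[1])
    if (anyNA(v))
      stop("missing value in column '", col, "' of ", path,
           " at data row ", which(is.na(v))[1])
    df[[col]] <- v
  }
  df
}

#' Read an expression matrix TSV
#'
#' Expects a header row of sample IDs and a first column
#' \code{transcript_id}; remaining cells numeric abundances.
#'
#' @param path TSV file.
#' @return numeric matrix, transcripts x samples.
#' @export
readExpression <- function(path) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (names(df)[1] != "transcript_id")
    stop("first column of ", path, " must be 'transcript_id'")
  ids <- df[[1]]
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate transcript row in ", path, ": ", dup[1])
  df <- .checkNumericCols(df, names(df)[-1], path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- ids
  m
}

#' @rdname readExpression
#' @param mat transcripts x samples numeric matrix with dimnames.
#' @export
writeExpression <- function(mat, path) {
  df <- data.frame(transcript_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype TSV (sample_id, value)
#'
#' @param path TSV file with header columns sample_id and value.
#' @return named numeric vector of trait values.
#' @export
readPhenotype <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!all(c("sample_id", "value") %in% names(df)))
    stop("phenotype file ", path, " must have columns sample_id, value")
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup)) stop("duplicate sample_id in ", path, ": ", dup[1])
  df <- .checkNumericCols(df, "value", path)
  stats::setNames(df$value, df$sample_id)
}

#' @rdname readPhenotype
#' @param pheno named numeric vector.
#' @export
writePhenotype <- function(pheno, path) {
  utils::write.table(
    data.frame(sample_id = names(pheno), value = unname(pheno)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write a gene-to-transcript map TSV
#'
#' Columns gene_id, transcript_id, identity_pct and optionally
#' is_representative.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
readGeneMap <- function(path) {
  if (!file.exists(path)) stop("gene map file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("gene_id", "transcript_id", "identity_pct")
  if (!all(need %in% names(df)))
    stop("gene map ", path, " must have columns ",
         paste(need, collapse = ", "))
  if (anyDuplicated(df[c("gene_id", "transcript_id")]))
    stop("duplicate (gene, transcript) pair in ", path)
  df <- .checkNumericCols(df, "identity_pct", path)
  if ("is_representative" %in% names(df))
    df$is_representative <- as.logical(df$is_representative)
  df
}

#' @rdname readGeneMap
#' @param map data.frame with the map columns.
#' @export
writeGeneMap <- function(map, path) {
  utils::write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a 12-column tabular homology-hit file
#'
#' Standard tabular column order: qseqid, sseqid, pident, length, mismatch,
#' gapopen, qstart, qend, sstart, send, evalue, bitscore; no header line.
#'
#' @param path TSV file.
#' @return data.frame of hits.
#' @export
readBlastTable <- function(path) {
  if (!file.exists(path)) stop("hit table not found: ", path)
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) != 12L)
    stop("hit table ", path, " must have 12 tab-separated columns, found ",
         ncol(df))
  names(df) <- cols
  .checkNumericCols(df, cols[-(1:2)], path)
}

#' @rdname readBlastTable
#' @param hits hit data.frame (an \code{is_decoy} column is dropped).
#' @export
writeBlastTable <- function(hits, path) {
  hits <- hits[, setdiff(names(hits), "is_decoy"), drop = FALSE]
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a co-expression network to disk
#'
#' Edge-list TSV (node_a, node_b, r, p) or GraphML (via \pkg{igraph},
#' including isolated candidate vertices so the candidate set survives the
#' round trip).
#'
#' @param network a \linkS4class{CoexpressionNetwork}.
#' @param path output file.
#' @param format "tsv" or "graphml".
#' @export
writeNetwork <- function(network, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(networkEdges(network), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    g <- asIgraph(network, isolated = TRUE)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' @rdname writeNetwork
#' @return \code{readNetworkEdges}: the edge data.frame.
#' @export
readNetworkEdges <- function(path) {
  if (!file.exists(path)) stop("network file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("node_a", "node_b", "r", "p")
  if (!all(need %in% names(df)))
    stop("network edge list ", path, " must have columns ",
         paste(need, collapse = ", "))
  .checkNumericCols(df, c("r", "p"), path)
}
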