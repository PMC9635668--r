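.asVector96 <- function(x, what = "pattern") {
  v <- if (is(x, "SbsSpectrum")) channelCounts(x) else x
  if (!is.numeric(v) || length(v) != 96L)
    stop(what, " must be an SbsSpectrum or a numeric vector of length 96")
  if (any(is.na(v)) || any(v < 0)) stop(what, " must be non-negative")
  if (sum(v) == 0) stop(what, " is a zero vector; cosine is undefined")
  unname(v)
}

#' Cosine similarity between two mutational patterns
#'
#' dot(a, b) / (||a|| ||b||): 1 for two proportional patterns, 0 for
#' patterns with disjoint support, scale-invariant in each argument.
#'
#' @param a,b `SbsSpectrum` objects or non-negative numeric vectors of
#'   length 96 (counts or frequencies; scale does not matter).
#' @return A number in \[0, 1\].
#' @export
cosineSimilarity <- function(a, b) {
  va <- .asVector96(a, "a")
  vb <- .asVector96(b, "b")
  sum(va * vb) / (sqrt(sum(va^2)) * sqrt(sum(vb^2)))
}

#' Pairwise cosine similarity matrix
#'
#' @param patterns Named list of `SbsSpectrum`/96-vectors, or a 96-row
#'   matrix with one named column per pattern.
#' @return Symmetric matrix with unit diagonal.
#' @export
similarityMatrix <- function(patterns) {
  if (is.matrix(patterns))
    patterns <- stats::setNames(
      lapply(seq_len(ncol(patterns)), function(i) patterns[, i]),
      colnames(patterns))
  if (length(patterns) < 2L) stop("need at least 2 patterns")
  if (is.null(names(patterns)) || any(!nzchar(names(patterns))))
    stop("patterns must be named")
  vs <- lapply(names(patterns), function(nm)
    tryCatch(.asVector96(patterns[[nm]], nm),
             error = function(e) stop("pattern ", sQuote(nm), ": ",
                                      conditionMessage(e), call. = FALSE)))
  n <- length(vs)
  m <- diag(1, n)
  dimnames(m) <- list(names(patterns), names(patterns))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    m[i, j] <- m[j, i] <- cosineSimilarity(vs[[i]], vs[[j]])
  }
  m
}

#' Rank catalog signatures by similarity to a query pattern
#'
#' @param query An `SbsSpectrum` or 96-vector.
#' @param catalog A [SignatureCatalog-class].
#' @param k Number of top matches to return (default: all).
#' @return data.frame with columns name, similarity, sorted by similarity
#'   descending; ties keep catalog order.
#' @export
bestMatches <- function(query, catalog, k = NULL) {
  stopifnot(is(catalog, "SignatureCatalog"))
  m <- signatureMatrix(catalog)
  if (ncol(m) == 0L) stop("empty signature catalog")
  if (is.null(k)) k <- ncol(m)
  if (k < 1) stop("k must be >= 1")
  q <- .asVector96(query, "query")
  sims <- vapply(seq_len(ncol(m)), function(i) cosineSimilarity(q, m[, i]),
                 numeric(1))
  ord <- order(-sims, method = "radix")  # stable: ties keep catalog order
  top <- utils::head(ord, k)
  data.frame(name = colnames(m)[top], similarity = sims[top],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Hierarchical-clustering leaf order of a similarity matrix
#'
#' Agglomerative clustering on distance 1 - similarity with average
#' linkage, as used to order heatmap rows/columns. Deterministic for a
#' fixed input; the linkage choice affects only display order, never the
#' similarity values themselves.
#'
#' @param m Symmetric similarity matrix with unit diagonal (from
#'   [similarityMatrix()]).
#' @return List: `order` (leaf indices), `labels` (leaf labels in dendrogram
#'   order), `hclust` (the `stats::hclust` object), `newick` (dendrogram as
#'   a Newick string).
#' @export
clusterOrder <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m) ||
      max(abs(m - t(m))) > 1e-8)
    stop("input must be a symmetric similarity matrix")
  d <- stats::as.dist(1 - m)
  hc <- stats::hclust(d, method = "average")
  nwk <- ape::write.tree(ape::as.phylo(hc))
  list(order = hc$order, labels = hc$labels[hc$order], hclust = hc,
       newick = nwk)
}

#' Read a COSMIC-style signature catalog
#'
#' Accepts tab-separated tables with 96 rows and either a single
#' channel-label column (`"A[C>A]A"` style; auto-detected by content) or
#' separate `Type` (`"C>A"`) and `Subtype`/trinucleotide (`"ACA"`) columns.
#' Remaining numeric columns are signatures. Rows are reordered to the
#' canonical channel order and columns renormalized to sum 1.
#'
#' @param path Path to the TSV.
#' @return A [SignatureCatalog-class].
#' @export
readSignatureCatalog <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) != 96L) stop("signature catalog must have 96 rows")
  chanCol <- which(vapply(df, function(col)
    is.character(col) && all(col %in% sbsChannels()), logical(1)))[1]
  if (!is.na(chanCol)) {
    labels <- df[[chanCol]]
    df[[chanCol]] <- NULL
  } else {
    typeCol <- which(vapply(df, function(col)
      is.character(col) && all(col %in% .SBS_TYPES), logical(1)))[1]
    subCol <- which(vapply(df, function(col)
      is.character(col) && all(grepl("^[ACGT]{3}$", col)), logical(1)))[1]
    if (is.na(typeCol) || is.na(subCol))
      stop("cannot locate channel labels: need either a 'A[C>A]A'-style ",
           "column or Type ('C>A') plus trinucleotide ('ACA') columns")
    labels <- paste0(substr(df[[subCol]], 1, 1), "[", df[[typeCol]], "]",
                     substr(df[[subCol]], 3, 3))
    df[[typeCol]] <- NULL
    df[[max(subCol - (subCol > typeCol), 1L)]] <- NULL
  }
  if (!setequal(labels, sbsChannels()))
    stop("catalog rows do not cover the 96 canonical channels")
  num <- vapply(df, is.numeric, logical(1))
  m <- as.matrix(df[, num, drop = FALSE])
  if (ncol(m) == 0L) stop("catalog contains no numeric signature columns")
  rownames(m) <- labels
  m <- m[sbsChannels(), , drop = FALSE]
  if (any(m < 0)) stop("signature values must be non-negative")
  cs <- colSums(m)
  if (any(cs <= 0)) stop("zero signature column(s): ",
                         paste(colnames(m)[cs <= 0], collapse = ", "))
  m <- sweep(m, 2, cs, "/")
  new("SignatureCatalog", signatures = m)
}

#' Write a similarity matrix as TSV
#'
#' @param m Similarity matrix.
#' @param path Output path.
#' @export
writeSimilarityMatrixTsv <- function(m, path) {
  utils::write.table(data.frame(pattern = rownames(m), m,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
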