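# cells x metacells averaging operator (columns sum to 1 within a metacell)
averagingOperator <- function(partition) {
  memb <- membership(partition)
  sz <- mcSizes(partition)
  Matrix::sparseMatrix(i = seq_along(memb), j = memb,
                       x = 1 / sz[memb],
                       dims = c(length(memb), length(sz)))
}

maybeSparse <- function(x) {
  x <- as.matrix(x)
  if (mean(x == 0) >= 0.5) methods::as(x, "CsparseMatrix") else x
}

checkPartitionDims <- function(x, partition, what = "matrix") {
  memb <- membership(partition)
  if (ncol(x) != length(memb))
    stop(what, " has ", ncol(x), " cells but the partition covers ",
         length(memb))
  if (!is.null(colnames(x)) && length(partition@cellIds) &&
      !identical(colnames(x), partition@cellIds))
    stop("cell identifiers of ", what,
         " do not match the partition's cell ids")
  invisible(TRUE)
}

#' Average expression within metacells
#'
#' The expression profile of a metacell is the arithmetic mean of the
#' (log-normalized) expression of its member cells, gene by gene. Mass is
#' conserved: for every gene, the size-weighted sum of metacell means
#' equals the sum over cells.
#'
#' @param expr genes x cells log-normalized expression matrix.
#' @param partition a \code{\linkS4class{MetacellPartition}} over the same
#'   cells.
#' @param layers optional named list of genes x cells matrices (e.g.
#'   spliced / unspliced counts) to average alongside.
#' @return a \code{\linkS4class{MetacellProfile}} (genes x metacells).
#' @export
averageExpression <- function(expr, partition, layers = list()) {
  checkPartitionDims(expr, partition, "expression matrix")
  op <- averagingOperator(partition)
  means <- maybeSparse(expr %*% op)
  rownames(means) <- rownames(expr)
  lay <- lapply(layers, function(l) {
    checkPartitionDims(l, partition, "layer")
    out <- maybeSparse(l %*% op)
    rownames(out) <- rownames(l)
    out
  })
  MetacellProfile(means, sizes = mcSizes(partition), layers = lay,
                  gamma = gammaLevel(partition))
}

#' Average an auxiliary layer within metacells
#'
#' Applies the same arithmetic averaging as \code{\link{averageExpression}}
#' to any genes x cells matrix (spliced counts, unspliced counts, ...).
#'
#' @param layer genes x cells matrix.
#' @param partition a \code{\linkS4class{MetacellPartition}}.
#' @return genes x metacells matrix of per-metacell means.
#' @export
averageLayer <- function(layer, partition) {
  checkPartitionDims(layer, partition, "layer")
  out <- maybeSparse(layer %*% averagingOperator(partition))
  rownames(out) <- rownames(layer)
  out
}

#' Average an embedding (or any per-cell coordinates) within metacells
#'
#' @param coords cells x d coordinate matrix (PCA, SPRING/UMAP layout,
#'   velocity field, ...).
#' @param partition a \code{\linkS4class{MetacellPartition}}.
#' @return metacells x d matrix of per-metacell mean coordinates.
#' @export
averageEmbedding <- function(coords, partition) {
  coords <- as.matrix(coords)
  memb <- membership(partition)
  if (nrow(coords) != length(memb))
    stop("coords rows must match the number of cells in the partition")
  out <- as.matrix(Matrix::crossprod(averagingOperator(partition), coords))
  colnames(out) <- colnames(coords)
  out
}

#' Fraction of genes detected per metacell
#'
#' A gene is detected in a metacell when its mean expression over the
#' member cells is positive (equivalently, when any member expresses it).
#' Averaging over cells rescues dropout zeros, so this fraction grows with
#' the graining level.
#'
#' @param expr genes x cells non-negative expression matrix.
#' @param partition a \code{\linkS4class{MetacellPartition}}.
#' @return numeric vector in [0, 1], one value per metacell.
#' @export
detectionFraction <- function(expr, partition) {
  if (any(expr < 0)) stop("expression must be non-negative")
  checkPartitionDims(expr, partition, "expression matrix")
  means <- expr %*% averagingOperator(partition)
  as.numeric(Matrix::colMeans(means > 0))
}
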