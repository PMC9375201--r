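#' Library-size normalize and log-transform a count matrix
#'
#' Scales every cell (column) to a common total count and applies
#' \code{log(1 + x)}. This is the standard preparation of a raw UMI count
#' matrix before variable-gene selection, PCA and graph construction.
#'
#' @param counts genes x cells matrix of non-negative counts (base matrix
#'   or \code{Matrix} sparse matrix).
#' @param scaleTarget positive total to scale every cell to
#'   (default 10,000).
#' @return a genes x cells matrix of the same storage type with
#'   log-normalized values.
#' @examples
#' m <- matrix(c(1, 1, 2, 0, 2, 2), nrow = 3,
#'             dimnames = list(paste0("g", 1:3), c("c1", "c2")))
#' normalizeLog(m, scaleTarget = 4)
#' @export
normalizeLog <- function(counts, scaleTarget = 1e4) {
  stopifnot(scaleTarget > 0)
  if (any(counts < 0)) stop("counts must be non-negative")
  tot <- Matrix::colSums(counts)
  if (any(tot == 0)) {
    bad <- which(tot == 0)
    nm <- if (!is.null(colnames(counts))) colnames(counts)[bad[1]]
          else paste("column", bad[1])
    stop("cell with zero total count: ", nm,
         if (length(bad) > 1) paste0(" (and ", length(bad) - 1, " more)"))
  }
  f <- scaleTarget / tot
  if (inherits(counts, "sparseMatrix")) {
    out <- counts %*% Matrix::Diagonal(x = f)
    out <- methods::as(out, "CsparseMatrix")
    out@x <- log1p(out@x)
    dimnames(out) <- dimnames(counts)
    out
  } else {
    log1p(sweep(counts, 2, f, "*"))
  }
}

# row variances for dense or sparse genes x cells matrices
rowVars2 <- function(x) {
  n <- ncol(x)
  mu <- Matrix::rowMeans(x)
  (Matrix::rowSums(x^2) - n * mu^2) / (n - 1)
}

#' Select the most variable genes
#'
#' Ranks genes by decreasing variance of their (log-normalized) expression
#' across cells; ties are broken deterministically by lower gene index.
#'
#' @param expr genes x cells log-normalized expression matrix.
#' @param nGenes number of genes to return (<= number of rows).
#' @return integer vector of row indices of the top \code{nGenes} genes,
#'   in decreasing order of variance.
#' @export
selectVariableGenes <- function(expr, nGenes) {
  if (nGenes > nrow(expr))
    stop("nGenes (", nGenes, ") exceeds the number of genes (",
         nrow(expr), ")")
  v <- rowVars2(expr)
  order(-v, seq_along(v))[seq_len(nGenes)]
}

# deterministic sign convention: largest-|loading| entry positive
fixSigns <- function(basis, coords) {
  for (j in seq_len(ncol(basis))) {
    i <- which.max(abs(basis[, j]))
    if (basis[i, j] < 0) {
      basis[, j] <- -basis[, j]
      coords[, j] <- -coords[, j]
    }
  }
  list(basis = basis, coords = coords)
}

#' Principal-component embedding of cells
#'
#' Centers genes across cells (optionally scales to unit variance) and
#' projects the cells onto the top principal components. The gene loadings,
#' centering and scaling vectors are retained so further cells can be
#' projected into the same space (used by approximate coarse-graining).
#'
#' Component signs follow a fixed convention: the largest-magnitude loading
#' of each component is positive.
#'
#' @param expr genes x cells log-normalized expression matrix.
#' @param geneSubset integer indices of the genes to use (default: all),
#'   typically from \code{\link{selectVariableGenes}}.
#' @param nComponents number of components (default 10); must not exceed
#'   \code{min(length(geneSubset), ncol(expr)) - 1}.
#' @param scale logical; scale genes to unit variance after centering
#'   (default \code{FALSE}; zero-variance genes are left at zero).
#' @return a \code{\linkS4class{CellEmbedding}}.
#' @export
embedPCA <- function(expr, geneSubset = NULL, nComponents = 10,
                     scale = FALSE) {
  if (is.null(geneSubset)) geneSubset <- seq_len(nrow(expr))
  geneSubset <- as.integer(geneSubset)
  nc <- ncol(expr)
  if (nComponents > min(length(geneSubset), nc) - 1)
    stop("nComponents must be <= min(genes, cells) - 1")
  x <- t(as.matrix(expr[geneSubset, , drop = FALSE]))  # cells x genes
  ctr <- colMeans(x)
  x <- sweep(x, 2, ctr, "-")
  scl <- numeric(0)
  if (scale) {
    scl <- sqrt(colSums(x^2) / (nc - 1))
    nz <- scl > 0
    x[, nz] <- sweep(x[, nz, drop = FALSE], 2, scl[nz], "/")
    x[, !nz] <- 0
  }
  if (any(!is.finite(x))) stop("non-finite values in expression matrix")
  sv <- svd(x, nu = 0, nv = nComponents)
  basis <- sv$v
  coords <- x %*% basis
  fx <- fixSigns(basis, coords)
  rownames(fx$coords) <- colnames(expr)
  rownames(fx$basis) <- rownames(expr)[geneSubset]
  new("CellEmbedding", coords = fx$coords, basis = fx$basis,
      center = ctr, scale = scl, genes = geneSubset,
      singular = sv$d[seq_len(nComponents)])
}

#' Project cells into an existing embedding
#'
#' @param expr genes x cells matrix over the same gene universe the
#'   embedding was computed from.
#' @param embedding a \code{\linkS4class{CellEmbedding}}.
#' @return cells x components coordinate matrix.
#' @export
projectCells <- function(expr, embedding) {
  x <- t(as.matrix(expr[embedding@genes, , drop = FALSE]))
  x <- sweep(x, 2, embedding@center, "-")
  if (length(embedding@scale)) {
    nz <- embedding@scale > 0
    x[, nz] <- sweep(x[, nz, drop = FALSE], 2, embedding@scale[nz], "/")
    x[, !nz] <- 0
  }
  x %*% embedding@basis
}

# exact k nearest neighbours by Euclidean distance, ties to lower index;
# returns n x k matrix of neighbour indices (self excluded)
knnIndices <- function(coords, k, block = 512L) {
  n <- nrow(coords)
  sq <- rowSums(coords^2)
  out <- matrix(0L, n, k)
  for (s in seq(1L, n, by = block)) {
    e <- min(s + block - 1L, n)
    d2 <- outer(sq[s:e], sq, "+") - 2 * tcrossprod(coords[s:e, , drop = FALSE], coords)
    for (i in seq_len(e - s + 1L)) {
      d2[i, s + i - 1L] <- Inf
      out[s + i - 1L, ] <- order(d2[i, ], seq_len(n))[seq_len(k)]
    }
  }
  out
}

#' Build a single-cell similarity graph
#'
#' Links each cell to its \code{k} nearest neighbours by Euclidean distance
#' in the embedding space. In \code{"knn"} mode the directed neighbour lists
#' are symmetrized by union into an undirected, unweighted graph. In
#' \code{"snn"} mode two cells are linked when they share at least one of
#' their \code{k} nearest neighbours and the Jaccard overlap of their
#' neighbour lists exceeds \code{snnJaccard}; any cell left isolated by the
#' pruning is re-attached to its nearest neighbour so the graph has no
#' degree-0 nodes.
#'
#' Distance ties are broken deterministically by lower cell index.
#'
#' @param embedding a \code{\linkS4class{CellEmbedding}} or a cells x d
#'   coordinate matrix.
#' @param k neighbourhood size, \code{1 <= k <} number of cells (default 5).
#' @param mode \code{"knn"} (default) or \code{"snn"}.
#' @param snnJaccard pruning threshold for snn mode (default 1/15).
#' @return an undirected \pkg{igraph} graph with graph attributes
#'   \code{k} and \code{mode}.
#' @export
buildCellGraph <- function(embedding, k = 5, mode = c("knn", "snn"),
                           snnJaccard = 1 / 15) {
  mode <- match.arg(mode)
  coords <- if (is(embedding, "CellEmbedding")) embedding@coords
            else as.matrix(embedding)
  n <- nrow(coords)
  if (k < 1 || k >= n) stop("k must satisfy 1 <= k < number of cells")
  if (any(!is.finite(coords))) stop("non-finite coordinates")
  nn <- knnIndices(coords, k)
  if (mode == "knn") {
    el <- cbind(rep(seq_len(n), each = k), as.vector(t(nn)))
  } else {
    a <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k),
                              j = as.vector(t(nn)), x = 1, dims = c(n, n))
    s <- Matrix::tcrossprod(a)
    s <- methods::as(methods::as(s, "generalMatrix"), "TsparseMatrix")
    keep <- s@i < s@j & s@x / (2 * k - s@x) > snnJaccard
    el <- cbind(s@i[keep] + 1L, s@j[keep] + 1L)
    deg <- tabulate(el, n)
    iso <- which(deg == 0L)
    if (length(iso)) el <- rbind(el, cbind(iso, nn[iso, 1L]))
  }
  g <- igraph::simplify(igraph::graph_from_edgelist(el, directed = FALSE))
  if (igraph::vcount(g) < n)
    g <- igraph::add_vertices(g, n - igraph::vcount(g))
  g <- igraph::set_graph_attr(g, "k", k)
  igraph::set_graph_attr(g, "mode", mode)
}
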