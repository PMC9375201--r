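#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' CellEmbedding: a low-dimensional embedding with its projection basis
#'
#' Stores the coordinates of cells (or metacells) in a principal-component
#' space together with the gene loadings, centering (and optional scaling)
#' vectors and the gene subset used, so that new observations can be
#' projected into the same space.
#'
#' @slot coords numeric matrix, observations x components.
#' @slot basis numeric matrix of gene loadings, genes x components, with
#'   orthonormal columns.
#' @slot center numeric vector of per-gene centers subtracted before
#'   projection.
#' @slot scale numeric vector of per-gene scale factors, or \code{numeric(0)}
#'   if no scaling was applied.
#' @slot genes integer indices of the genes (rows of the original matrix)
#'   the embedding was computed on.
#' @slot singular numeric vector of singular values (may be empty).
#'
#' @exportClass CellEmbedding
setClass("CellEmbedding",
  representation(
    coords = "matrix",
    basis = "matrix",
    center = "numeric",
    scale = "numeric",
    genes = "integer",
    singular = "numeric"
  )
)

setValidity("CellEmbedding", function(object) {
  msg <- NULL
  if (ncol(object@coords) != ncol(object@basis))
    msg <- c(msg, "coords and basis must have the same number of components")
  if (nrow(object@basis) != length(object@center))
    msg <- c(msg, "basis rows must match length of center")
  if (length(object@scale) && length(object@scale) != length(object@center))
    msg <- c(msg, "scale must be empty or match center length")
  bt <- crossprod(object@basis)
  if (nrow(bt) > 0 && max(abs(bt - diag(nrow(bt)))) > 1e-8)
    msg <- c(msg, "basis columns must be orthonormal (tolerance 1e-8)")
  if (is.null(msg)) TRUE else msg
})

#' @describeIn CellEmbedding compact display
#' @param object a \code{CellEmbedding}
#' @export
setMethod("show", "CellEmbedding", function(object) {
  cat("CellEmbedding:", nrow(object@coords), "observations x",
      ncol(object@coords), "components (", nrow(object@basis),
      "genes in basis )\n")
})

#' MetacellDendrogram: per-component walktrap merge hierarchies
#'
#' Holds the agglomerative merge sequence computed by walktrap on every
#' connected component of a single-cell graph. The hierarchy can be cut at
#' any number of metacells between the number of components and the number
#' of cells without recomputing the random walks (see
#' \code{\link{cutToMetacells}}).
#'
#' @slot communities list with one element per connected component: an
#'   igraph \code{communities} object for components with more than one
#'   node, \code{NULL} for singleton components.
#' @slot componentOf integer vector mapping each cell to its component id.
#' @slot componentCells list of integer vectors; the cell indices of each
#'   component in the order used by the corresponding communities object.
#' @slot nCells integer, number of cells.
#' @slot cellIds character vector of cell identifiers (may be empty).
#'
#' @exportClass MetacellDendrogram
setClass("MetacellDendrogram",
  representation(
    communities = "list",
    componentOf = "integer",
    componentCells = "list",
    nCells = "integer",
    cellIds = "character"
  )
)

setValidity("MetacellDendrogram", function(object) {
  msg <- NULL
  if (length(object@componentOf) != object@nCells)
    msg <- c(msg, "componentOf must have one entry per cell")
  if (length(object@communities) != length(object@componentCells))
    msg <- c(msg, "communities and componentCells must align")
  if (length(object@cellIds) &&
      length(object@cellIds) != object@nCells)
    msg <- c(msg, "cellIds must be empty or one per cell")
  if (is.null(msg)) TRUE else msg
})

#' @describeIn MetacellDendrogram compact display
#' @param object a \code{MetacellDendrogram}
#' @export
setMethod("show", "MetacellDendrogram", function(object) {
  cat("MetacellDendrogram:", object@nCells, "cells,",
      length(object@communities), "connected component(s)\n")
})

#' MetacellPartition: an assignment of cells to metacells
#'
#' The central result of coarse-graining: a mapping from every cell to a
#' metacell. Metacell ids are contiguous integers starting at 1, ordered by
#' the first cell belonging to each metacell. The graining level gamma is
#' the ratio of the number of cells to the number of metacells.
#'
#' @slot membership integer vector, one metacell id (1-based) per cell.
#' @slot cellIds character vector of cell identifiers (may be empty).
#' @slot gamma numeric, the realised graining level N_c / N_mc.
#' @slot algorithm character, how the partition was produced (e.g.
#'   \code{"walktrap"}, \code{"louvain"}, \code{"walktrap-approx"},
#'   \code{"identity"}, \code{"manual"}).
#' @slot parameters list of parameters recorded for provenance (k, number
#'   of principal components, seed, ...).
#'
#' @seealso \code{\link{cutToMetacells}}, \code{\link{coarseGrain}},
#'   \code{\link{averageExpression}}
#' @exportClass MetacellPartition
setClass("MetacellPartition",
  representation(
    membership = "integer",
    cellIds = "character",
    gamma = "numeric",
    algorithm = "character",
    parameters = "list"
  )
)

setValidity("MetacellPartition", function(object) {
  msg <- NULL
  m <- object@membership
  if (length(m) < 1L) msg <- c(msg, "membership must be non-empty")
  if (anyNA(m) || any(m < 1L))
    msg <- c(msg, "membership ids must be positive integers")
  else {
    nmc <- max(m)
    if (!all(seq_len(nmc) %in% m))
      msg <- c(msg, "metacell ids must be contiguous (every id non-empty)")
    g <- length(m) / nmc
    if (abs(object@gamma - g) > 1e-8 * max(1, g))
      msg <- c(msg, "gamma must equal n_cells / n_metacells")
  }
  if (length(object@cellIds) && length(object@cellIds) != length(m))
    msg <- c(msg, "cellIds must be empty or one per cell")
  if (is.null(msg)) TRUE else msg
})

#' Construct a MetacellPartition from a membership vector
#'
#' @param membership integer (or factor/character) vector assigning each
#'   cell to a metacell; relabelled to contiguous 1-based ids in order of
#'   first appearance.
#' @param cellIds optional character vector of cell identifiers.
#' @param algorithm character tag recording how the partition was made.
#' @param parameters list of provenance parameters.
#' @return a \code{\link{MetacellPartition}}.
#' @examples
#' p <- MetacellPartition(c(1, 1, 2, 2, 3))
#' mcSizes(p)
#' @export
MetacellPartition <- function(membership, cellIds = character(),
                              algorithm = "manual", parameters = list()) {
  memb <- match(membership, unique(membership))
  new("MetacellPartition",
      membership = as.integer(memb),
      cellIds = as.character(cellIds),
      gamma = length(memb) / max(memb),
      algorithm = algorithm,
      parameters = parameters)
}

#' @describeIn MetacellPartition compact display
#' @param object a \code{MetacellPartition}
#' @export
setMethod("show", "MetacellPartition", function(object) {
  sz <- mcSizes(object)
  cat("MetacellPartition:", length(object@membership), "cells ->",
      length(sz), "metacells (gamma =",
      format(object@gamma, digits = 4), ", algorithm =",
      object@algorithm, ")\n")
  cat("  metacell sizes: min", min(sz), "median", stats::median(sz),
      "max", max(sz), "\n")
})

#' MetacellProfile: metacell-level expression container
#'
#' A \linkS4class{SummarizedExperiment} with genes as rows and metacells as
#' columns. The \code{"mean"} assay holds the average log-normalized
#' expression of the member cells of each metacell; further assays hold
#' averaged auxiliary layers (e.g. spliced / unspliced counts). Metacell
#' sizes are stored in \code{colData(x)$size} and the graining level in
#' \code{metadata(x)$gamma}.
#'
#' @exportClass MetacellProfile
setClass("MetacellProfile", contains = "SummarizedExperiment")

setValidity("MetacellProfile", function(object) {
  msg <- NULL
  if (!"mean" %in% names(SummarizedExperiment::assays(object)))
    msg <- c(msg, "a 'mean' assay is required")
  if (!"size" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must contain a 'size' column")
  else if (any(object$size <= 0))
    msg <- c(msg, "metacell sizes must be positive")
  if (is.null(msg)) TRUE else msg
})

#' Construct a MetacellProfile
#'
#' @param mean genes x metacells matrix of averaged expression.
#' @param sizes numeric vector of metacell sizes (member-cell counts).
#' @param layers named list of additional genes x metacells matrices.
#' @param gamma graining level to record in the metadata.
#' @return a \code{\link{MetacellProfile}}.
#' @export
MetacellProfile <- function(mean, sizes, layers = list(), gamma = NA_real_) {
  stopifnot(length(sizes) == ncol(mean))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = c(list(mean = mean), layers),
    colData = S4Vectors::DataFrame(size = as.numeric(sizes)))
  if (is.null(colnames(se)))
    colnames(se) <- paste0("mc", seq_len(ncol(se)))
  out <- new("MetacellProfile", se)
  S4Vectors::metadata(out)$gamma <- gamma
  out
}

#' @describeIn MetacellProfile compact display
#' @param object a \code{MetacellProfile}
#' @export
setMethod("show", "MetacellProfile", function(object) {
  cat("MetacellProfile:", nrow(object), "genes x", ncol(object),
      "metacells; assays:",
      paste(names(SummarizedExperiment::assays(object)), collapse = ", "),
      "\n")
  g <- S4Vectors::metadata(object)$gamma
  if (!is.null(g) && !is.na(g))
    cat("  gamma =", format(g, digits = 4), "\n")
})

#' WeightedSilhouette: silhouette widths of a weighted clustering
#'
#' @slot s numeric per-metacell silhouette widths in [-1, 1].
#' @slot cluster integer cluster labels.
#' @slot weights numeric metacell sizes used as sample weights.
#' @slot S numeric, overall size-weighted mean silhouette.
#' @exportClass WeightedSilhouette
setClass("WeightedSilhouette",
  representation(s = "numeric", cluster = "integer",
                 weights = "numeric", S = "numeric"))

#' @describeIn WeightedSilhouette compact display
#' @param object a \code{WeightedSilhouette}
#' @export
setMethod("show", "WeightedSilhouette", function(object) {
  cat("WeightedSilhouette:", length(object@s), "metacells,",
      length(unique(object@cluster)), "clusters; overall S =",
      format(object@S, digits = 4), "\n")
})
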