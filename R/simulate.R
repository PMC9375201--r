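#' Simulate a typed scRNA-seq count matrix
#'
#' Negative-binomial counts for a population of discrete cell types
#' sharing a baseline expression program. Per type, a fraction
#' \code{deFrac} of genes is shifted up by \code{effectLfc} (log2) —
#' these spiked genes are the type's true markers. Counts are drawn with
#' cell-specific library sizes and overdispersion \code{dispersion}
#' (NB size = 1/dispersion), then thinned by independent Bernoulli dropout.
#' Reproducible bit-exactly from \code{seed} (R's default Mersenne-Twister
#' stream). If partial dropout leaves a cell with zero total count, one
#' count of the first gene is added so every cell satisfies the
#' normalization precondition (with \code{dropoutRate = 1} the matrix is
#' left all-zero and is rejected downstream).
#'
#' Defaults give the well-separated 5-type, 2000-cell, 500-gene population
#' used throughout the package's own evaluation.
#'
#' @param nCells number of cells (default 2000).
#' @param nGenes number of genes (default 500).
#' @param nTypes number of cell types; cells are assigned in equal
#'   contiguous blocks (default 5).
#' @param deFrac fraction of genes spiked per type (default 0.04, i.e. 20
#'   markers per type at the default gene count).
#' @param effectLfc log2 shift of spiked genes (default 2, a 4-fold
#'   change, typical of clear marker genes).
#' @param dropoutRate Bernoulli dropout probability (default 0.1).
#' @param libSizeRange integer range of per-cell library sizes (default
#'   c(1500, 3000)).
#' @param dispersion NB overdispersion (default 0.5).
#' @param seed integer seed (required).
#' @return list with \code{counts} (genes x cells \code{dgCMatrix} with
#'   dimnames), \code{labels} (factor per cell), \code{trueDE} (list:
#'   type -> spiked gene ids), \code{signatures} (same sets, as marker
#'   signatures), \code{params}, \code{seed}.
#' @examples
#' sim <- simulateCounts(nCells = 100, nGenes = 60, nTypes = 2, seed = 7)
#' table(sim$labels)
#' @export
simulateCounts <- function(nCells = 2000, nGenes = 500, nTypes = 5,
                           deFrac = 0.04, effectLfc = 2,
                           dropoutRate = 0.1,
                           libSizeRange = c(1500, 3000),
                           dispersion = 0.5, seed) {
  stopifnot(nCells >= nTypes, nGenes >= 1, deFrac >= 0, deFrac <= 1,
            dropoutRate >= 0, dropoutRate <= 1, dispersion > 0)
  if (missing(seed)) stop("seed is required for reproducibility")
  set.seed(seed)
  geneIds <- sprintf("gene%04d", seq_len(nGenes))
  cellIds <- sprintf("cell%05d", seq_len(nCells))
  types <- paste0("type", seq_len(nTypes))
  labels <- factor(types[sort(rep_len(seq_len(nTypes), nCells))],
                   levels = types)
  baseLog2 <- stats::rnorm(nGenes, 0, 1)
  nSpike <- round(deFrac * nGenes)
  spikePool <- sample.int(nGenes, min(nGenes, nSpike * nTypes))
  trueDE <- lapply(seq_len(nTypes), function(t)
    geneIds[sort(spikePool[seq_len(nSpike) + (t - 1) * nSpike])])
  names(trueDE) <- types
  typeMeans <- vapply(seq_len(nTypes), function(t) {
    lg <- baseLog2
    lg[match(trueDE[[t]], geneIds)] <- lg[match(trueDE[[t]], geneIds)] +
      effectLfc
    2^lg
  }, numeric(nGenes))
  typeProb <- sweep(typeMeans, 2, colSums(typeMeans), "/")
  lib <- sample(seq(libSizeRange[1], libSizeRange[2]), nCells,
                replace = TRUE)
  counts <- matrix(0L, nGenes, nCells, dimnames = list(geneIds, cellIds))
  for (c in seq_len(nCells)) {
    mu <- lib[c] * typeProb[, as.integer(labels[c])]
    counts[, c] <- stats::rnbinom(nGenes, size = 1 / dispersion, mu = mu)
  }
  if (dropoutRate > 0) {
    keep <- matrix(stats::rbinom(nGenes * nCells, 1, 1 - dropoutRate),
                   nGenes, nCells)
    counts <- counts * keep
  }
  if (dropoutRate < 1) {
    zero <- Matrix::colSums(counts) == 0
    if (any(zero)) counts[1, zero] <- counts[1, zero] + 1L
  }
  list(counts = methods::as(counts, "CsparseMatrix"), labels = labels,
       trueDE = trueDE, signatures = trueDE,
       params = list(nCells = nCells, nGenes = nGenes, nTypes = nTypes,
                     deFrac = deFrac, effectLfc = effectLfc,
                     dropoutRate = dropoutRate,
                     libSizeRange = libSizeRange,
                     dispersion = dispersion),
       seed = seed)
}

#' Simulate an RNA-velocity field along a type-ordered trajectory
#'
#' Emulates a directed differentiation flow: cells of each type get a unit
#' vector pointing from their type's centroid toward the next type's
#' centroid in the embedding (the last type keeps the incoming direction),
#' plus isotropic Gaussian noise.
#'
#' @param labels factor of cell types (the trajectory follows the factor
#'   level order).
#' @param coords cells x d embedding coordinates.
#' @param noiseSd standard deviation of the additive noise (default 0;
#'   with 0 all cells of a type share one vector).
#' @param seed integer seed.
#' @return cells x d velocity matrix.
#' @export
simulateVelocity <- function(labels, coords, noiseSd = 0, seed = 1) {
  coords <- as.matrix(coords)
  labels <- as.factor(labels)
  stopifnot(nrow(coords) == length(labels))
  set.seed(seed)
  lev <- levels(labels)
  cent <- t(vapply(lev, function(l)
    colMeans(coords[labels == l, , drop = FALSE]), numeric(ncol(coords))))
  dir <- matrix(0, length(lev), ncol(coords))
  for (i in seq_along(lev)) {
    j <- if (i < length(lev)) i + 1L else i
    ii <- if (i < length(lev)) i else i - 1L
    d <- cent[min(j, length(lev)), ] - cent[ii, ]
    n <- sqrt(sum(d^2))
    dir[i, ] <- if (n > 0) d / n else d
  }
  v <- dir[as.integer(labels), , drop = FALSE]
  if (noiseSd > 0)
    v <- v + matrix(stats::rnorm(length(v), 0, noiseSd), nrow(v))
  rownames(v) <- rownames(coords)
  v
}

#' Simulate a gene-to-GO annotation with module structure
#'
#' Genes inside a module share a block of GO terms (each term attached
#' with probability \code{overlap}); every gene additionally draws from a
#' small background pool with probability \code{background}, so
#' cross-module sharing is rare. Genes outside all modules get background
#' terms only.
#'
#' @param modules named list of gene-id character vectors.
#' @param allGenes character vector of the full gene universe.
#' @param termsPerModule GO terms in each module block (default 5).
#' @param overlap probability a module gene carries a given module term
#'   (default 0.8).
#' @param background probability of carrying a given background term
#'   (default 0.05; 10 background terms).
#' @param seed integer seed.
#' @return named list: gene id -> character vector of GO ids (possibly
#'   empty).
#' @export
simulateGO <- function(modules, allGenes, termsPerModule = 5,
                       overlap = 0.8, background = 0.05, seed = 1) {
  set.seed(seed)
  nb <- 10
  bgTerms <- sprintf("GO:BG%02d", seq_len(nb))
  go <- stats::setNames(vector("list", length(allGenes)), allGenes)
  for (g in allGenes)
    go[[g]] <- bgTerms[stats::runif(nb) < background]
  for (m in seq_along(modules)) {
    terms <- sprintf("GO:M%02d_%02d", m, seq_len(termsPerModule))
    for (g in intersect(modules[[m]], allGenes))
      go[[g]] <- c(go[[g]], terms[stats::runif(termsPerModule) < overlap])
  }
  go
}

#' Simulate a complete analysis bundle
#'
#' Convenience generator combining \code{\link{simulateCounts}}, a PCA
#' embedding, \code{\link{simulateVelocity}} and \code{\link{simulateGO}}
#' (modules = the per-type marker sets), for end-to-end tests and the
#' \code{simulate} CLI subcommand.
#'
#' @inheritParams simulateCounts
#' @param velocityNoise noise level passed to
#'   \code{\link{simulateVelocity}} (default 0.2).
#' @return the \code{\link{simulateCounts}} list extended with
#'   \code{expr} (log-normalized), \code{embedding}, \code{velocity} and
#'   \code{go}.
#' @export
simulateBundle <- function(nCells = 2000, nGenes = 500, nTypes = 5,
                           deFrac = 0.04, effectLfc = 2,
                           dropoutRate = 0.1, velocityNoise = 0.2, seed) {
  sim <- simulateCounts(nCells = nCells, nGenes = nGenes, nTypes = nTypes,
                        deFrac = deFrac, effectLfc = effectLfc,
                        dropoutRate = dropoutRate, seed = seed)
  sim$expr <- normalizeLog(sim$counts)
  hvg <- selectVariableGenes(sim$expr, min(100, nGenes))
  sim$embedding <- embedPCA(sim$expr, hvg,
                            nComponents = min(10, length(hvg) - 1,
                                              nCells - 1))
  sim$velocity <- simulateVelocity(sim$labels,
                                   sim$embedding@coords[, 1:2],
                                   noiseSd = velocityNoise,
                                   seed = seed + 1)
  sim$go <- simulateGO(sim$trueDE, rownames(sim$counts), seed = seed + 2)
  sim
}
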