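#' Walktrap merge hierarchy of a single-cell graph
#'
#' Runs the walktrap community-detection algorithm (short random walks,
#' agglomerative merging) independently on every connected component of the
#' graph and stores the merge sequences. The result can be cut at any
#' graining level with \code{\link{cutToMetacells}} without recomputing the
#' random walks.
#'
#' @param graph an undirected \pkg{igraph} graph from
#'   \code{\link{buildCellGraph}}.
#' @param steps random-walk length (default 4).
#' @param cellIds optional character ids for the graph's nodes.
#' @return a \code{\linkS4class{MetacellDendrogram}}.
#' @export
walktrapDendrogram <- function(graph, steps = 4, cellIds = character()) {
  n <- igraph::vcount(graph)
  if (n < 1) stop("graph must have at least one node")
  comp <- igraph::components(graph)
  ncomp <- comp$no
  comms <- vector("list", ncomp)
  cells <- vector("list", ncomp)
  for (cc in seq_len(ncomp)) {
    vids <- which(comp$membership == cc)
    cells[[cc]] <- vids
    if (length(vids) > 1L) {
      sub <- igraph::induced_subgraph(graph, vids)
      comms[[cc]] <- igraph::cluster_walktrap(sub, steps = steps,
                                              merges = TRUE,
                                              membership = FALSE)
    }
  }
  new("MetacellDendrogram", communities = comms,
      componentOf = as.integer(comp$membership),
      componentCells = cells, nCells = as.integer(n),
      cellIds = as.character(cellIds))
}

# Allocate `total` metacells across components proportionally to their
# sizes with a floor of 1 and a cap of the component size. Highest-averages
# (D'Hondt) rule: monotone in `total`, so cutting the same hierarchy at a
# larger metacell count always refines the coarser partition. Ties go to
# the larger component, then to the lower component index.
allocateAcrossComponents <- function(sizes, total) {
  ncomp <- length(sizes)
  stopifnot(total >= ncomp, total <= sum(sizes))
  a <- rep(1L, ncomp)
  for (r in seq_len(total - ncomp)) {
    open <- which(a < sizes)
    pr <- sizes[open] / (a[open] + 1)
    best <- open[order(-pr, -sizes[open], open)[1L]]
    a[best] <- a[best] + 1L
  }
  a
}

relabelByFirstCell <- function(memb) as.integer(match(memb, unique(memb)))

#' @describeIn cutToMetacells cut a walktrap hierarchy so that exactly
#'   \code{round(nCells / gamma)} (or \code{nMetacells}) metacells remain.
#'   Cuts are allocated across connected components proportionally to
#'   component size (each component gets at least one metacell); metacell
#'   ids are relabelled contiguously in order of each metacell's first
#'   cell. When \code{gamma} is given the metacell count is clamped below
#'   at the number of components; an explicit \code{nMetacells} outside
#'   \code{[components, cells]} is an error.
#' @param gamma target graining level (cells per metacell), >= 1.
#' @param nMetacells exact number of metacells to produce.
#' @export
setMethod("cutToMetacells", "MetacellDendrogram",
  function(tree, gamma = NULL, nMetacells = NULL) {
    if (is.null(gamma) == is.null(nMetacells))
      stop("give exactly one of gamma or nMetacells")
    n <- tree@nCells
    ncomp <- length(tree@communities)
    if (!is.null(gamma)) {
      if (gamma < 1) stop("gamma must be >= 1")
      nmc <- max(ncomp, min(n, round(n / gamma)))
    } else {
      nmc <- as.integer(nMetacells)
      if (nmc < ncomp)
        stop("nMetacells (", nmc, ") below the number of connected ",
             "components (", ncomp, ")")
      if (nmc > n) stop("nMetacells exceeds the number of cells")
    }
    sizes <- lengths(tree@componentCells)
    alloc <- allocateAcrossComponents(sizes, nmc)
    memb <- integer(n)
    offset <- 0L
    for (cc in seq_len(ncomp)) {
      vids <- tree@componentCells[[cc]]
      if (length(vids) == 1L) {
        memb[vids] <- offset + 1L
      } else {
        loc <- igraph::cut_at(tree@communities[[cc]], no = alloc[cc])
        memb[vids] <- offset + as.integer(loc)
      }
      offset <- offset + alloc[cc]
    }
    new("MetacellPartition",
        membership = relabelByFirstCell(memb),
        cellIds = tree@cellIds,
        gamma = n / nmc,
        algorithm = "walktrap",
        parameters = list(requested_gamma = gamma, n_metacells = nmc))
  })

# merge communities of a membership vector until `target` remain,
# joining the pair with the heaviest inter-community edge count
mergeToCount <- function(graph, memb, target) {
  while (max(memb) > target) {
    el <- igraph::as_edgelist(graph, names = FALSE)
    mi <- memb[el[, 1]]; mj <- memb[el[, 2]]
    keep <- mi != mj
    if (!any(keep)) stop("cannot merge across components")
    key <- paste(pmin(mi[keep], mj[keep]), pmax(mi[keep], mj[keep]))
    tab <- sort(table(key), decreasing = TRUE)
    pair <- as.integer(strsplit(names(tab)[1L], " ")[[1L]])
    memb[memb == pair[2L]] <- pair[1L]
    memb <- relabelByFirstCell(memb)
  }
  memb
}

#' Louvain-based metacell partition
#'
#' Alternative coarse-graining backend: Louvain modularity communities on
#' the single-cell graph, adjusted to the requested graining level. Louvain
#' has no direct control over the number of communities, so oversized
#' communities are recursively re-partitioned (Louvain on the induced
#' subgraph, falling back to a walktrap 2-cut when Louvain will not split),
#' taking the split adding the fewest communities first, until the target
#' count is reached; an overshoot is corrected by merging the community
#' pair with the heaviest connecting edge count.
#'
#' @inheritParams walktrapDendrogram
#' @param gamma target graining level.
#' @return a \code{\linkS4class{MetacellPartition}} with
#'   \code{algorithm = "louvain"}.
#' @export
louvainPartition <- function(graph, gamma, cellIds = character()) {
  n <- igraph::vcount(graph)
  if (gamma < 1) stop("gamma must be >= 1")
  comp <- igraph::components(graph)
  nmc <- max(comp$no, min(n, round(n / gamma)))
  if (nmc == n) {
    memb <- seq_len(n)
  } else {
    memb0 <- as.integer(igraph::membership(igraph::cluster_louvain(graph)))
    comms <- unname(split(seq_len(n), memb0))
    subSplit <- function(vids) {
      sub <- igraph::induced_subgraph(graph, vids)
      loc <- as.integer(igraph::membership(igraph::cluster_louvain(sub)))
      if (max(loc) == 1L && length(vids) > 1L) {
        wt <- igraph::cluster_walktrap(sub, merges = TRUE,
                                       membership = FALSE)
        loc <- as.integer(igraph::cut_at(wt, no = 2L))
      }
      unname(split(vids, loc))
    }
    splits <- vector("list", length(comms))   # cached sub-partitions
    while (length(comms) < nmc) {
      multi <- which(lengths(comms) > 1L)
      if (!length(multi)) break
      for (i in multi)
        if (is.null(splits[[i]])) splits[[i]] <- subSplit(comms[[i]])
      inc <- vapply(splits[multi], length, integer(1)) - 1L
      ok <- multi[inc > 0L]
      if (!length(ok)) {
        # unsplittable communities (e.g. cliques of duplicates):
        # peel single cells off the largest until the count is exact
        while (length(comms) < nmc) {
          big <- which.max(lengths(comms))
          v <- comms[[big]]
          comms[[big]] <- v[-length(v)]
          comms[[length(comms) + 1L]] <- v[length(v)]
        }
        break
      }
      pick <- ok[order(inc[match(ok, multi)], -lengths(comms)[ok], ok)[1L]]
      parts <- splits[[pick]]
      room <- nmc - length(comms) + 1L
      if (length(parts) > room) {
        # keep the largest `room` parts, fold the rest into the largest
        o <- order(-lengths(parts))
        keepp <- parts[o[seq_len(room)]]
        keepp[[1L]] <- sort(c(keepp[[1L]],
                              unlist(parts[o[-seq_len(room)]])))
        parts <- keepp
      }
      comms[[pick]] <- parts[[1L]]
      splits[pick] <- list(NULL)
      if (length(parts) > 1L) {
        comms <- c(comms, parts[-1L])
        splits <- c(splits, vector("list", length(parts) - 1L))
      }
    }
    memb <- integer(n)
    for (i in seq_along(comms)) memb[comms[[i]]] <- i
    memb <- relabelByFirstCell(memb)
    if (max(memb) > nmc) memb <- mergeToCount(graph, memb, nmc)
  }
  new("MetacellPartition", membership = relabelByFirstCell(memb),
      cellIds = as.character(cellIds), gamma = n / nmc,
      algorithm = "louvain",
      parameters = list(requested_gamma = gamma, n_metacells = nmc))
}

#' Per-sample graining level for dataset integration
#'
#' When coarse-graining each sample of a multi-sample study separately,
#' the graining level is chosen as \code{min(floor(n / 20), 10)} so that
#' every sample yields at least about 20 metacells; the value is clamped
#' below at 1 for samples of fewer than 20 cells (where the formula would
#' give 0, undefined as a graining level).
#'
#' @param n sample size (number of cells), >= 1.
#' @return integer graining level in \code{[1, 10]}.
#' @examples
#' gammaForSample(150) # 7
#' gammaForSample(1000) # 10
#' gammaForSample(19) # clamped to 1
#' @export
gammaForSample <- function(n) {
  stopifnot(n >= 1)
  as.integer(max(1, min(n %/% 20, 10)))
}

#' Full coarse-graining pipeline
#'
#' Variable-gene selection, PCA, kNN/sNN graph, walktrap (or Louvain), and
#' the cut at the requested graining level, in one call.
#'
#' @param expr genes x cells log-normalized expression matrix.
#' @param gamma target graining level (default 10).
#' @param k neighbourhood size (default 5).
#' @param nPCs number of principal components (default 10; clamped to the
#'   feasible maximum with a message).
#' @param nHVG number of variable genes (default 1000; clamped to the gene
#'   count).
#' @param mode graph mode, \code{"knn"} or \code{"snn"}.
#' @param algorithm \code{"walktrap"} (default) or \code{"louvain"}.
#' @param steps walktrap walk length (default 4).
#' @param geneSubset optional explicit gene indices overriding \code{nHVG}.
#' @param scale scale genes before PCA (default \code{FALSE}).
#' @return a list with elements \code{partition}
#'   (\code{\linkS4class{MetacellPartition}}), \code{dendrogram} (for
#'   walktrap, else \code{NULL}), \code{graph}, \code{embedding} and
#'   \code{genes} (the gene indices used).
#' @examples
#' sim <- simulateCounts(nCells = 120, nGenes = 80, nTypes = 3, seed = 1)
#' expr <- normalizeLog(sim$counts)
#' cg <- coarseGrain(expr, gamma = 5, nHVG = 50, nPCs = 5)
#' cg$partition
#' @export
coarseGrain <- function(expr, gamma = 10, k = 5, nPCs = 10, nHVG = 1000,
                        mode = c("knn", "snn"),
                        algorithm = c("walktrap", "louvain"), steps = 4,
                        geneSubset = NULL, scale = FALSE) {
  mode <- match.arg(mode)
  algorithm <- match.arg(algorithm)
  cellIds <- if (is.null(colnames(expr))) character() else colnames(expr)
  if (is.null(geneSubset)) {
    nHVG <- min(nHVG, nrow(expr))
    geneSubset <- selectVariableGenes(expr, nHVG)
  }
  maxPC <- min(length(geneSubset), ncol(expr)) - 1
  if (nPCs > maxPC) {
    message("nPCs reduced to ", maxPC)
    nPCs <- maxPC
  }
  emb <- embedPCA(expr, geneSubset, nComponents = nPCs, scale = scale)
  g <- buildCellGraph(emb, k = k, mode = mode)
  if (algorithm == "walktrap") {
    tree <- walktrapDendrogram(g, steps = steps, cellIds = cellIds)
    part <- cutToMetacells(tree, gamma = gamma)
  } else {
    tree <- NULL
    part <- louvainPartition(g, gamma = gamma, cellIds = cellIds)
  }
  part@parameters <- c(part@parameters,
                       list(k = k, n_pcs = nPCs, graph_mode = mode,
                            steps = steps))
  list(partition = part, dendrogram = tree, graph = g, embedding = emb,
       genes = geneSubset)
}

#' Approximate coarse-graining for large datasets
#'
#' Runs the exact pipeline on a uniform random subsample of cells,
#' targeting the metacell count implied by \code{gamma} over the full
#' dataset, then projects every remaining cell into the subsample's PCA
#' space and assigns it to the metacell with the nearest centroid
#' (Euclidean distance). With \code{nSubsample = ncol(expr)} the result is
#' identical to the exact pipeline.
#'
#' @inheritParams coarseGrain
#' @param nSubsample number of cells to subsample (<= number of cells).
#' @param seed integer seed for the subsample (mandatory, for
#'   reproducibility).
#' @return a \code{\linkS4class{MetacellPartition}} over all cells with
#'   \code{algorithm = "walktrap-approx"}.
#' @export
approximateCoarseGrain <- function(expr, gamma, nSubsample, seed,
                                   k = 5, nPCs = 10, nHVG = 1000,
                                   mode = c("knn", "snn"), steps = 4,
                                   scale = FALSE) {
  mode <- match.arg(mode)
  n <- ncol(expr)
  stopifnot(nSubsample >= 1, nSubsample <= n)
  nmc <- max(1L, min(n, round(n / gamma)))
  if (nSubsample < nmc)
    stop("nSubsample (", nSubsample, ") is below the requested number of ",
         "metacells (", nmc, ")")
  if (nSubsample == n) {
    sub <- seq_len(n)
  } else {
    set.seed(seed)
    sub <- sort(sample.int(n, nSubsample))
  }
  cg <- coarseGrain(expr[, sub, drop = FALSE], gamma = nSubsample / nmc,
                    k = k, nPCs = nPCs, nHVG = nHVG, mode = mode,
                    algorithm = "walktrap", steps = steps, scale = scale)
  subMemb <- membership(cg$partition)
  nmcGot <- nMetacells(cg$partition)
  memb <- integer(n)
  memb[sub] <- subMemb
  rest <- setdiff(seq_len(n), sub)
  if (length(rest)) {
    cent <- averageEmbedding(cg$embedding@coords,
                             cg$partition)          # metacells x d
    rc <- projectCells(expr[, rest, drop = FALSE], cg$embedding)
    d2 <- outer(rowSums(rc^2), rowSums(cent^2), "+") -
      2 * tcrossprod(rc, cent)
    memb[rest] <- vapply(seq_len(nrow(d2)), function(i)
      order(d2[i, ], seq_len(nmcGot))[1L], integer(1))
  }
  cellIds <- if (is.null(colnames(expr))) character() else colnames(expr)
  new("MetacellPartition", membership = relabelByFirstCell(memb),
      cellIds = cellIds, gamma = n / nmcGot,
      algorithm = "walktrap-approx",
      parameters = list(requested_gamma = gamma, n_subsample = nSubsample,
                        seed = seed, k = k, n_pcs = nPCs))
}

#' Split metacells so that each is pure with respect to an annotation
#'
#' Every metacell containing cells from more than one annotation category
#' (cell type, sample, condition, ...) is split into one metacell per
#' (metacell, category) pair, so the resulting partition is perfectly pure
#' by construction. The output refines the input: cells are never merged.
#'
#' @param partition a \code{\linkS4class{MetacellPartition}}.
#' @param labels vector of annotation categories, one per cell, no missing
#'   values.
#' @return a new \code{\linkS4class{MetacellPartition}} with ids
#'   renumbered contiguously (deterministically, by first cell).
#' @export
splitByAnnotation <- function(partition, labels) {
  memb <- membership(partition)
  if (length(labels) != length(memb) || anyNA(labels))
    stop("labels must be defined for every cell")
  key <- paste(memb, as.character(labels), sep = "\r")
  new("MetacellPartition", membership = relabelByFirstCell(key),
      cellIds = partition@cellIds,
      gamma = length(memb) / length(unique(key)),
      algorithm = paste0(partition@algorithm, "+split"),
      parameters = partition@parameters)
}

#' Metacell network induced by a partition
#'
#' The weight of the edge between metacells i and j is the number of
#' single-cell graph edges with one endpoint in i and the other in j.
#'
#' @param graph the single-cell \pkg{igraph} graph.
#' @param partition a \code{\linkS4class{MetacellPartition}} over the same
#'   cells.
#' @return an undirected weighted \pkg{igraph} graph on the metacells
#'   (vertex count = number of metacells, integer edge weights).
#' @export
metacellNetwork <- function(graph, partition) {
  memb <- membership(partition)
  if (igraph::vcount(graph) != length(memb))
    stop("graph and partition must cover the same cells")
  nmc <- nMetacells(partition)
  el <- igraph::as_edgelist(graph, names = FALSE)
  mi <- memb[el[, 1]]; mj <- memb[el[, 2]]
  keep <- mi != mj
  g <- igraph::make_empty_graph(nmc, directed = FALSE)
  if (any(keep)) {
    a <- pmin(mi[keep], mj[keep]); b <- pmax(mi[keep], mj[keep])
    tab <- table(paste(a, b))
    pairs <- do.call(rbind, lapply(strsplit(names(tab), " "), as.integer))
    g <- igraph::add_edges(g, as.vector(t(pairs)),
                           weight = as.integer(tab))
  }
  g
}
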