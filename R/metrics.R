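#' Purity of metacells with respect to a cell annotation
#'
#' The purity of a metacell is the proportion of its cells belonging to
#' its most abundant cell type. At graining level 1 every purity is 1 by
#' construction.
#'
#' @param partition a \code{\linkS4class{MetacellPartition}}.
#' @param labels cell-type labels, one per cell.
#' @return list with \code{values} (per-metacell purity) and
#'   \code{median}.
#' @export
purity <- function(partition, labels) {
  memb <- membership(partition)
  stopifnot(length(labels) == length(memb))
  vals <- vapply(split(as.character(labels), memb),
                 function(l) max(table(l)) / length(l), numeric(1))
  vals <- unname(vals[order(as.integer(names(vals)))])
  list(values = vals, median = stats::median(vals))
}

#' Majority-vote annotation of metacells
#'
#' Each metacell is annotated with the most abundant label among its
#' member cells; ties are broken deterministically by lexicographically
#' smallest label.
#'
#' @inheritParams purity
#' @return character vector, one label per metacell.
#' @export
majorityAnnotation <- function(partition, labels) {
  memb <- membership(partition)
  ann <- vapply(split(as.character(labels), memb), function(l) {
    tab <- table(l)
    names(tab)[order(-tab, names(tab))[1L]]
  }, character(1))
  ann[order(as.integer(names(ann)))]
}

#' Conservation of a rare cell type across metacells
#'
#' Metacells are annotated by majority vote. \code{assignmentFraction} is
#' the fraction of cells of the target type that sit in a metacell
#' annotated to that type. \code{weightedPurity} is the purity of the
#' target-annotated metacells (fraction of target cells) averaged with
#' weights equal to the number of target cells each contains, so large
#' metacells do not dominate small ones per cell counted.
#'
#' @inheritParams purity
#' @param targetLabel the (rare) cell type of interest.
#' @return list with \code{assignmentFraction} and \code{weightedPurity}
#'   (NA when no metacell is annotated to the target type).
#' @export
rareTypePurity <- function(partition, labels, targetLabel) {
  memb <- membership(partition)
  labels <- as.character(labels)
  stopifnot(length(labels) == length(memb))
  ann <- majorityAnnotation(partition, labels)
  isTarget <- labels == targetLabel
  if (!any(isTarget)) stop("no cell carries the target label")
  hit <- ann[memb] == targetLabel
  af <- sum(isTarget & hit) / sum(isTarget)
  mcs <- which(ann == targetLabel)
  if (!length(mcs))
    return(list(assignmentFraction = 0, weightedPurity = NA_real_))
  nt <- vapply(mcs, function(m) sum(isTarget & memb == m), numeric(1))
  sz <- mcSizes(partition)[mcs]
  list(assignmentFraction = af,
       weightedPurity = sum((nt / sz) * nt) / sum(nt))
}

#' Adjusted Rand index between two partitions
#'
#' Hubert and Arabie's chance-corrected agreement, computed from the
#' contingency table of the two labelings. 1 for identical partitions,
#' around 0 for independent ones.
#'
#' @param a,b two labelings of the same items.
#' @return numeric ARI (<= 1).
#' @export
adjustedRandIndex <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- sum(tab)
  sumij <- sum(choose(tab, 2))
  sumA <- sum(choose(rowSums(tab), 2))
  sumB <- sum(choose(colSums(tab), 2))
  expected <- sumA * sumB / choose(n, 2)
  maxidx <- (sumA + sumB) / 2
  if (maxidx == expected) return(0)  # both trivial partitions
  (sumij - expected) / (maxidx - expected)
}

#' Reference set of differentially expressed genes (single-cell level)
#'
#' The union, over all clusters, of the genes significantly upregulated in
#' the one-vs-rest weighted t-test: BH-adjusted p below \code{pThr} and
#' logFC above \code{lfcThr}.
#'
#' @param deTable output of \code{\link{weightedDE}} at the single-cell
#'   level (unit weights).
#' @param pThr adjusted p-value threshold (default 0.05).
#' @param lfcThr logFC threshold (default 0.5; 0.25 suits datasets with
#'   milder effects).
#' @return character vector of gene ids (the set M); empty is an error
#'   because the recovery rate would be undefined.
#' @export
deReferenceSet <- function(deTable, pThr = 0.05, lfcThr = 0.5) {
  m <- unique(deTable$gene[deTable$p_adj < pThr & deTable$logFC > lfcThr])
  if (!length(m))
    stop("no gene passes the significance/logFC thresholds; ",
         "the DE recovery rate is undefined")
  sort(m)
}

#' Recovered set of differentially expressed genes (metacell level)
#'
#' Among genes significantly upregulated in any cluster (BH-adjusted
#' p below \code{pThr}, logFC > 0), each gene keeps its largest logFC
#' across clusters and the top \code{n} genes by decreasing logFC (ties by
#' gene id) are returned. If fewer than \code{n} genes are significant,
#' all are returned and the shortfall is recorded in attribute
#' \code{"shortfall"}.
#'
#' @param deTable output of \code{\link{weightedDE}} at the metacell
#'   level.
#' @param n target set size, normally \code{length(M)} of the reference.
#' @param pThr adjusted p-value threshold (default 0.05).
#' @return character vector of gene ids (the set M-tilde).
#' @export
deRecoveredSet <- function(deTable, n, pThr = 0.05) {
  if (n == 0) return(character())
  sig <- deTable[deTable$p_adj < pThr & deTable$logFC > 0, , drop = FALSE]
  if (!nrow(sig)) {
    out <- character()
    attr(out, "shortfall") <- n
    return(out)
  }
  best <- tapply(sig$logFC, sig$gene, max)
  o <- order(-best, names(best))
  out <- names(best)[o][seq_len(min(n, length(best)))]
  if (length(out) < n) attr(out, "shortfall") <- n - length(out)
  out
}

#' Recovery rate of differentially expressed genes
#'
#' \code{TPR = |intersect(M, Mtilde)| / |M|}; with the two sets of equal
#' size this equals the precision of the metacell-level list.
#'
#' @param m reference gene set (single-cell level).
#' @param mTilde recovered gene set (metacell level).
#' @return numeric in [0, 1].
#' @export
tpr <- function(m, mTilde) {
  if (!length(m)) stop("reference set M is empty; TPR undefined")
  length(intersect(m, mTilde)) / length(m)
}

jaccard <- function(a, b) {
  u <- union(a, b)
  if (!length(u)) return(0)
  length(intersect(a, b)) / length(u)
}

# all-pairs correlation + BH significance, returning the top-n pair keys
topCorrelatedPairs <- function(rho, nEff, topN, pThr, byMagnitude) {
  g <- rownames(rho)
  idx <- which(upper.tri(rho), arr.ind = TRUE)
  r <- rho[idx]
  r <- pmax(-1, pmin(1, r))
  t <- r * sqrt((nEff - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(t), nEff - 2)
  padj <- stats::p.adjust(p, method = "BH")
  key <- paste(g[idx[, 1]], g[idx[, 2]], sep = "|")
  sig <- padj < pThr
  score <- if (byMagnitude) abs(r) else r
  o <- order(-score[sig], key[sig])
  key[sig][o][seq_len(min(topN, sum(sig)))]
}

#' GO match score ratio of top correlated gene pairs
#'
#' Measures whether coarse-graining improves the functional coherence of
#' gene-gene correlations. Genes expressed (value > 0) in more than
#' \code{expressedFrac} of the cells are kept; all gene pairs are ranked
#' by Pearson correlation at the single-cell level and by size-weighted
#' Pearson correlation at the metacell level; per level the top
#' \code{topN} pairs among those with BH-adjusted p < \code{pThr} are
#' selected. Each pair's GO match score is the Jaccard coefficient of the
#' two genes' GO id sets, and the reported ratio is the mean score of
#' metacell-exclusive pairs over the mean score of single-cell-exclusive
#' pairs (> 1 means the metacell level surfaces more functionally related
#' pairs).
#'
#' @param exprSC genes x cells single-cell log-normalized matrix (row
#'   names required).
#' @param profile a \code{\linkS4class{MetacellProfile}} of the same
#'   genes.
#' @param go named list mapping gene id to a character vector of GO ids
#'   (genes absent from the list have an empty set).
#' @param expressedFrac detection-fraction filter (default 0.5).
#' @param topN number of top pairs per level (default 1000).
#' @param pThr BH-adjusted p threshold (default 0.05).
#' @param byMagnitude rank pairs by |correlation| instead of signed value
#'   (default \code{FALSE}).
#' @return list with \code{ratio}, \code{meanMC}, \code{meanSC} and the
#'   exclusive pair keys.
#' @export
goMatchScoreRatio <- function(exprSC, profile, go, expressedFrac = 0.5,
                              topN = 1000, pThr = 0.05,
                              byMagnitude = FALSE) {
  stopifnot(!is.null(rownames(exprSC)))
  keep <- Matrix::rowMeans(exprSC > 0) > expressedFrac
  if (sum(keep) < 3) stop("fewer than 3 genes pass the expression filter")
  x <- as.matrix(exprSC[keep, , drop = FALSE])
  rhoSC <- stats::cor(t(x))
  prof <- as.matrix(SummarizedExperiment::assay(profile, "mean"))
  pm <- prof[rownames(x), , drop = FALSE]
  w <- mcSizes(profile)
  z <- weightedScale(t(pm), w, scale = FALSE)     # weighted centering
  cv <- crossprod(z * sqrt(w / sum(w)))
  rhoMC <- stats::cov2cor(cv)
  dimnames(rhoMC) <- dimnames(rhoSC)
  scPairs <- topCorrelatedPairs(rhoSC, ncol(x), topN, pThr, byMagnitude)
  mcPairs <- topCorrelatedPairs(rhoMC, sum(w), topN, pThr, byMagnitude)
  scExcl <- setdiff(scPairs, mcPairs)
  mcExcl <- setdiff(mcPairs, scPairs)
  if (!length(scExcl) || !length(mcExcl))
    stop("no exclusive pairs at one of the levels; the pair lists are ",
         "degenerate (identical or empty) and the ratio is undefined")
  pairScore <- function(keys) vapply(strsplit(keys, "|", fixed = TRUE),
    function(gg) jaccard(go[[gg[1]]], go[[gg[2]]]), numeric(1))
  meanSC <- mean(pairScore(scExcl))
  meanMC <- mean(pairScore(mcExcl))
  list(ratio = meanMC / meanSC, meanMC = meanMC, meanSC = meanSC,
       mcExclusive = mcExcl, scExclusive = scExcl)
}

cosineMatrix <- function(v) {
  nrm <- sqrt(rowSums(v^2))
  u <- v / ifelse(nrm > 0, nrm, 1)     # zero vectors stay zero -> cos 0
  tcrossprod(u)
}

#' Velocity purity of metacells
#'
#' Coherence of the RNA-velocity vectors pooled into each metacell:
#' \code{velocity_purity(C) = max over x in C of the median over y in C of
#' cos(v(x), v(y))}. The cosine with a zero vector is defined as 0; a
#' singleton metacell has purity 1. Invariant to positive rescaling of the
#' vectors.
#'
#' @param partition a \code{\linkS4class{MetacellPartition}}.
#' @param v cells x d matrix of velocity vectors.
#' @return numeric vector in [-1, 1], one value per metacell.
#' @export
velocityPurity <- function(partition, v) {
  v <- as.matrix(v)
  memb <- membership(partition)
  stopifnot(nrow(v) == length(memb))
  vapply(seq_len(nMetacells(partition)), function(m) {
    idx <- which(memb == m)
    if (length(idx) == 1L) return(1)
    cm <- cosineMatrix(v[idx, , drop = FALSE])
    max(apply(cm, 1, stats::median))
  }, numeric(1))
}

rowCosine <- function(a, b) {
  na <- sqrt(rowSums(a^2)); nb <- sqrt(rowSums(b^2))
  num <- rowSums(a * b)
  ifelse(na > 0 & nb > 0, num / (na * nb), 0)
}

#' Velocity similarity between single cells and their metacells
#'
#' The median over all cells of the cosine between the cell's velocity
#' vector and the velocity vector of the metacell containing it.
#'
#' @param vCells cells x d velocity matrix.
#' @param vMetacells metacells x d velocity matrix (e.g. re-estimated from
#'   pooled spliced/unspliced layers, or averaged).
#' @param partition a \code{\linkS4class{MetacellPartition}}.
#' @return numeric scalar.
#' @export
velocitySimilarity <- function(vCells, vMetacells, partition) {
  vCells <- as.matrix(vCells); vMetacells <- as.matrix(vMetacells)
  memb <- membership(partition)
  stopifnot(nrow(vCells) == length(memb),
            nrow(vMetacells) == nMetacells(partition))
  stats::median(rowCosine(vCells, vMetacells[memb, , drop = FALSE]))
}

#' Velocity similarity under subsampling
#'
#' Comparison baseline for subsampling instead of coarse-graining: the
#' median over all cells of the cosine between the cell's velocity and the
#' velocity of the nearest retained cell (Euclidean distance in
#' \code{coords}; a retained cell is its own nearest neighbour).
#'
#' @param vCells cells x d velocity matrix.
#' @param kept integer indices of the retained (subsampled) cells.
#' @param coords cells x d2 coordinates used for the nearest-neighbour
#'   match.
#' @return numeric scalar.
#' @export
velocitySimilaritySubsample <- function(vCells, kept, coords) {
  vCells <- as.matrix(vCells); coords <- as.matrix(coords)
  stopifnot(nrow(vCells) == nrow(coords), all(kept >= 1),
            all(kept <= nrow(coords)))
  ck <- coords[kept, , drop = FALSE]
  d2 <- outer(rowSums(coords^2), rowSums(ck^2), "+") -
    2 * tcrossprod(coords, ck)
  nearest <- kept[apply(d2, 1, which.min)]
  stats::median(rowCosine(vCells, vCells[nearest, , drop = FALSE]))
}
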