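# Sample-weighted statistics. Each metacell is treated as size(i)
# observations placed at its profile; with unit weights every function
# reduces to its classical counterpart, and with integer weights it equals
# the classical statistic computed on the multiplicity-expanded sample.

asObsMatrix <- function(x) {
  # metacells x genes observation matrix from a profile or matrix
  if (is(x, "MetacellProfile"))
    t(as.matrix(SummarizedExperiment::assay(x, "mean")))
  else as.matrix(x)
}

defaultWeights <- function(x, w) {
  if (!is.null(w)) return(as.numeric(w))
  if (is(x, "MetacellProfile")) return(as.numeric(mcSizes(x)))
  rep(1, nrow(asObsMatrix(x)))
}

#' Weighted scaling (z-scoring) of a metacell matrix
#'
#' Centers each gene at its weight-normalized mean and divides by the
#' weighted standard deviation in the frequency-weight convention,
#' \code{var = sum(w * (x - mu)^2) / (sum(w) - 1)}: a weight of w counts
#' as w observations. With unit weights this is ordinary unbiased
#' z-scoring, and with integer weights it equals z-scoring of the
#' multiplicity-expanded sample. Zero-variance genes are set to 0.
#'
#' @param x metacells x genes matrix, or a
#'   \code{\linkS4class{MetacellProfile}} (transposed internally).
#' @param w positive weights, one per metacell (defaults to the profile's
#'   sizes; unit weights for a plain matrix).
#' @param center,scale logical switches (both default \code{TRUE}).
#' @return metacells x genes scaled matrix with attributes
#'   \code{"center"} and \code{"scale"}.
#' @export
weightedScale <- function(x, w = NULL, center = TRUE, scale = TRUE) {
  m <- asObsMatrix(x)
  w <- defaultWeights(x, w)
  stopifnot(length(w) == nrow(m), all(w > 0))
  wn <- w / sum(w)
  mu <- as.vector(crossprod(m, wn))
  if (center) m <- sweep(m, 2, mu, "-")
  sd <- rep(1, ncol(m))
  if (scale) {
    v <- as.vector(crossprod(m^2, w)) / (sum(w) - 1)
    sd <- sqrt(pmax(v, 0))
    pos <- sd > 0
    m[, pos] <- sweep(m[, pos, drop = FALSE], 2, sd[pos], "/")
    m[, !pos] <- 0
  }
  attr(m, "center") <- mu
  attr(m, "scale") <- sd
  m
}

#' Sample-weighted PCA of metacells
#'
#' After weighted scaling, the decomposition is the SVD of the weighted
#' covariance \code{(1/N_c) t(X) \%*\% W \%*\% X}, where \code{X} is the
#' scaled metacells x genes matrix and \code{W} the diagonal matrix of
#' metacell sizes; the embedding is \code{X \%*\% V} with \code{V} the top
#' right-singular vectors. Component signs follow the same convention as
#' \code{\link{embedPCA}}.
#'
#' @inheritParams weightedScale
#' @param nComponents number of components; must be
#'   \code{<= min(genes, metacells) - 1}.
#' @param scale apply \code{\link{weightedScale}} first (default
#'   \code{TRUE}; set \code{FALSE} if \code{x} is already scaled).
#' @return a \code{\linkS4class{CellEmbedding}} over metacells (coords =
#'   metacells x components); \code{@singular} holds the singular values
#'   of the weighted covariance.
#' @export
weightedPCA <- function(x, w = NULL, nComponents = 10, scale = TRUE) {
  m <- asObsMatrix(x)
  w <- defaultWeights(x, w)
  if (nComponents > min(ncol(m), nrow(m)) - 1)
    stop("nComponents must be <= min(genes, metacells) - 1")
  if (scale) m <- weightedScale(m, w)
  if (any(!is.finite(m))) stop("non-finite entries in input matrix")
  nc <- sum(w)
  y <- m * sqrt(w / nc)          # t(y) %*% y == (1/N_c) t(m) W m
  sv <- svd(y, nu = 0, nv = nComponents)
  basis <- sv$v
  coords <- m %*% basis
  fx <- fixSigns(basis, coords)
  rownames(fx$coords) <- rownames(m)
  rownames(fx$basis) <- colnames(m)
  ctr <- attr(m, "center"); scl <- attr(m, "scale")
  new("CellEmbedding", coords = fx$coords, basis = fx$basis,
      center = if (is.null(ctr)) numeric(ncol(m)) else ctr,
      scale = if (is.null(scl)) numeric(0) else scl,
      genes = seq_len(ncol(m)),
      singular = sv$d[seq_len(nComponents)]^2)
}

#' Size-weighted Ward hierarchical clustering of metacells
#'
#' Ward agglomeration in which each metacell enters the hierarchy as a
#' pre-formed group of \code{w[i]} observations located at its coordinates.
#' The between-group dissimilarities are initialised to the exact Ward
#' merge costs \code{2 * w_i * w_j / (w_i + w_j) * ||c_i - c_j||^2} and the
#' Lance-Williams updates run with member counts \code{w}
#' (\code{stats::hclust(method = "ward.D", members = w)}), which makes the
#' weighted tree identical to Ward clustering of the multiplicity-expanded
#' point set. Deterministic.
#'
#' @param coords metacells x d coordinate matrix (typically
#'   \code{\link{weightedPCA}} coordinates).
#' @param w positive metacell sizes.
#' @param nClusters number of clusters to cut the tree into.
#' @param linkage agglomeration rule; only \code{"ward"} is provided.
#' @return integer cluster labels (one per metacell), with the
#'   \code{hclust} tree in attribute \code{"tree"}.
#' @export
weightedHclust <- function(coords, w = NULL, nClusters,
                           linkage = c("ward")) {
  match.arg(linkage)
  coords <- as.matrix(coords)
  if (is.null(w)) w <- rep(1, nrow(coords))
  stopifnot(all(w > 0), length(w) == nrow(coords))
  if (nClusters < 1 || nClusters > nrow(coords))
    stop("nClusters out of range")
  d2 <- as.matrix(stats::dist(coords))^2
  ww <- outer(w, w) / outer(w, w, "+")
  h <- stats::hclust(stats::as.dist(2 * ww * d2), method = "ward.D",
                     members = w)
  labels <- stats::cutree(h, k = nClusters)
  attr(labels, "tree") <- h
  labels
}

#' Size-weighted silhouette coefficient
#'
#' For a metacell i in cluster C_m with cluster cell-count
#' \code{|C_m| = sum of sizes}, the mean within-cluster distance is
#' \code{a(i) = sum_{j in C_m, j != i} d(i,j) * size(j) / (|C_m| - size(i))}
#' and the smallest mean distance to another cluster is
#' \code{b(i) = min_k sum_{j in C_k} d(i,j) * size(j) / |C_k|}; the width
#' is \code{s(i) = (b - a) / max(a, b)}. Any metacell alone in its cluster
#' gets \code{s(i) = 0}. The overall coefficient is the sample-weighted
#' mean \code{S = sum(s * size) / N_c}.
#'
#' @param x metacells x d coordinates, or a pre-computed symmetric distance
#'   matrix when \code{isDist = TRUE}.
#' @param labels cluster labels, one per metacell (at least 2 clusters).
#' @param w positive metacell sizes (default: unit weights, giving the
#'   classical silhouette).
#' @param isDist interpret \code{x} as a distance matrix.
#' @return a \code{\linkS4class{WeightedSilhouette}}.
#' @export
weightedSilhouette <- function(x, labels, w = NULL, isDist = FALSE) {
  d <- if (isDist) as.matrix(x) else as.matrix(stats::dist(as.matrix(x)))
  n <- nrow(d)
  labels <- as.integer(factor(labels))
  if (length(unique(labels)) < 2)
    stop("weighted silhouette needs at least 2 clusters")
  if (is.null(w)) w <- rep(1, n)
  stopifnot(length(labels) == n, length(w) == n, all(w > 0))
  clusterSize <- tapply(w, labels, sum)          # |C_k| in cells
  nPerCluster <- tabulate(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    m <- labels[i]
    if (nPerCluster[m] == 1L) { s[i] <- 0; next }
    same <- which(labels == m & seq_len(n) != i)
    a <- sum(d[i, same] * w[same]) / (clusterSize[[m]] - w[i])
    others <- setdiff(unique(labels), m)
    b <- min(vapply(others, function(k) {
      jk <- which(labels == k)
      sum(d[i, jk] * w[jk]) / clusterSize[[as.character(k)]]
    }, numeric(1)))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  new("WeightedSilhouette", s = s, cluster = labels, weights = w,
      S = sum(s * w) / sum(w))
}

#' Sample-weighted Welch t-test
#'
#' Frequency-weight convention: a weight w counts as w observations, so
#' \code{n_g = sum(w)}, the weighted variance uses denominator
#' \code{sum(w) - 1}, and with integer weights the test is identical to
#' Welch's t-test on the multiplicity-expanded samples. The statistic is
#' \code{t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)} with Welch-Satterthwaite
#' degrees of freedom and a two-tailed p-value; \code{logFC = m1 - m2}
#' (difference of weighted means in log space).
#'
#' @param x,y numeric value vectors for the two groups.
#' @param wx,wy positive weights (default unit weights). Each group's
#'   weight sum must be >= 2.
#' @return list with \code{t}, \code{df}, \code{p}, \code{logFC},
#'   \code{meanX}, \code{meanY}.
#' @export
weightedTTest <- function(x, y, wx = NULL, wy = NULL) {
  if (is.null(wx)) wx <- rep(1, length(x))
  if (is.null(wy)) wy <- rep(1, length(y))
  stopifnot(length(wx) == length(x), length(wy) == length(y),
            all(wx > 0), all(wy > 0))
  n1 <- sum(wx); n2 <- sum(wy)
  if (n1 < 2 || n2 < 2) stop("each group needs total weight >= 2")
  m1 <- sum(wx * x) / n1; m2 <- sum(wy * y) / n2
  v1 <- sum(wx * (x - m1)^2) / (n1 - 1)
  v2 <- sum(wy * (y - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  diff <- m1 - m2
  if (se2 == 0) {
    t <- if (diff == 0) 0 else sign(diff) * Inf
    return(list(t = t, df = n1 + n2 - 2, p = if (diff == 0) 1 else 0,
                logFC = diff, meanX = m1, meanY = m2))
  }
  t <- diff / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df), logFC = diff,
       meanX = m1, meanY = m2)
}

# vectorized one-vs-rest weighted Welch test over the genes of a profile
weightedTTestMatrix <- function(m, w, inGroup) {
  wA <- w[inGroup]; wB <- w[!inGroup]
  nA <- sum(wA); nB <- sum(wB)
  xA <- m[inGroup, , drop = FALSE]; xB <- m[!inGroup, , drop = FALSE]
  mA <- as.vector(crossprod(xA, wA)) / nA
  mB <- as.vector(crossprod(xB, wB)) / nB
  vA <- pmax(as.vector(crossprod(xA^2, wA)) - nA * mA^2, 0) / (nA - 1)
  vB <- pmax(as.vector(crossprod(xB^2, wB)) - nB * mB^2, 0) / (nB - 1)
  se2 <- vA / nA + vB / nB
  diff <- mA - mB
  t <- ifelse(se2 > 0, diff / sqrt(se2),
              ifelse(diff == 0, 0, sign(diff) * Inf))
  df <- ifelse(se2 > 0,
               se2^2 / ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1)),
               nA + nB - 2)
  p <- ifelse(is.finite(t), 2 * stats::pt(-abs(t), df),
              ifelse(t == 0, 1, 0))
  p[t == 0] <- 1
  list(t = t, df = df, p = p, logFC = diff, meanIn = mA, meanOut = mB)
}

#' One-vs-rest weighted differential expression
#'
#' For every group of metacells (cluster), tests each gene with the
#' sample-weighted Welch t-test against the union of all other groups and
#' adjusts p-values by Benjamini-Hochberg within the comparison. Genes are
#' ranked within each group by p-value, ties by decreasing logFC.
#'
#' @param x a \code{\linkS4class{MetacellProfile}}, or a metacells x
#'   genes matrix (observations as rows, as in \code{\link{weightedScale}}).
#' @param labels group (cluster) labels, one per metacell; at least 2
#'   groups.
#' @param w positive metacell sizes (default: profile sizes or unit).
#' @return a \code{data.frame} with columns \code{gene}, \code{group},
#'   \code{mean_in}, \code{mean_out}, \code{logFC}, \code{t}, \code{df},
#'   \code{p}, \code{p_adj}, \code{rank}.
#' @export
weightedDE <- function(x, labels, w = NULL) {
  m <- asObsMatrix(x)
  w <- defaultWeights(x, w)
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(m), length(w) == nrow(m))
  if (length(unique(labels)) < 2) stop("need at least 2 groups")
  genes <- colnames(m)
  if (is.null(genes)) genes <- paste0("gene", seq_len(ncol(m)))
  out <- lapply(sort(unique(labels)), function(g) {
    r <- weightedTTestMatrix(m, w, labels == g)
    padj <- stats::p.adjust(r$p, method = "BH")
    df <- data.frame(gene = genes, group = g, mean_in = r$meanIn,
                     mean_out = r$meanOut, logFC = r$logFC, t = r$t,
                     df = r$df, p = r$p, p_adj = padj,
                     stringsAsFactors = FALSE)
    df$rank <- order(order(df$p, -df$logFC))
    df
  })
  do.call(rbind, out)
}

#' Sample-weighted Pearson correlation
#'
#' Correlation from weighted covariance and standard deviations (weights
#' normalized to sum to 1); the p-value uses the t approximation
#' \code{t = rho * sqrt((sum(w) - 2) / (1 - rho^2))} with
#' \code{df = sum(w) - 2}.
#'
#' @param x,y numeric vectors.
#' @param w positive weights (default unit).
#' @return list with \code{estimate}, \code{t}, \code{df}, \code{p}.
#' @export
weightedPearson <- function(x, y, w = NULL) {
  if (is.null(w)) w <- rep(1, length(x))
  stopifnot(length(x) == length(y), length(w) == length(x), all(w > 0))
  wn <- w / sum(w)
  mx <- sum(wn * x); my <- sum(wn * y)
  cxy <- sum(wn * (x - mx) * (y - my))
  sx <- sqrt(sum(wn * (x - mx)^2)); sy <- sqrt(sum(wn * (y - my)^2))
  if (sx == 0 || sy == 0) stop("zero variance in x or y")
  rho <- max(-1, min(1, cxy / (sx * sy)))
  df <- sum(w) - 2
  if (abs(rho) >= 1) return(list(estimate = rho, t = sign(rho) * Inf,
                                 df = df, p = 0))
  t <- rho * sqrt(df / (1 - rho^2))
  list(estimate = rho, t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Gene-signature score
#'
#' The score of a cell or metacell is the sum over signature genes of the
#' gene's expression divided by its maximum across columns
#' (max-normalization). Signature genes absent from the matrix are skipped
#' with a warning; an empty intersection is an error.
#'
#' @param x genes x columns matrix (single cells or metacell profile
#'   means) with row names, or a \code{\linkS4class{MetacellProfile}}.
#' @param geneSet character vector of signature gene ids.
#' @return numeric score per column.
#' @export
signatureScore <- function(x, geneSet) {
  if (is(x, "MetacellProfile"))
    x <- as.matrix(SummarizedExperiment::assay(x, "mean"))
  x <- as.matrix(x)
  hit <- geneSet %in% rownames(x)
  if (!any(hit)) stop("no signature gene found in the matrix")
  if (!all(hit))
    warning(sum(!hit), " signature gene(s) absent from the matrix, skipped")
  sub <- x[geneSet[hit], , drop = FALSE]
  mx <- apply(sub, 1, max)
  sub[mx > 0, ] <- sub[mx > 0, , drop = FALSE] / mx[mx > 0]
  colSums(sub)
}

#' Weighted rank-based AUC
#'
#' Area under the ROC curve of \code{scores} as a predictor of
#' \code{labels}; with weights, each observation counts \code{w} times
#' (a metacell counts as its size). Ties contribute 1/2.
#'
#' @param scores numeric predictor.
#' @param labels logical (or 0/1) positive-class indicator.
#' @param w positive weights (default unit).
#' @return AUC in [0, 1].
#' @export
scoreAUC <- function(scores, labels, w = NULL) {
  labels <- as.logical(labels)
  if (is.null(w)) w <- rep(1, length(scores))
  stopifnot(length(scores) == length(labels), length(w) == length(scores))
  sp <- scores[labels]; sn <- scores[!labels]
  wp <- w[labels]; wn <- w[!labels]
  if (!length(sp) || !length(sn))
    stop("both classes must be present")
  gt <- outer(sp, sn, ">") + 0.5 * outer(sp, sn, "==")
  sum(outer(wp, wn) * gt) / (sum(wp) * sum(wn))
}
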