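# Shared fixtures, all generated in code.

# well-separated gaussian blobs in d dimensions
makeBlobs <- function(nPerBlob, centers, sd = 1, seed = 1) {
  set.seed(seed)
  d <- ncol(centers)
  coords <- do.call(rbind, lapply(seq_len(nrow(centers)), function(b)
    matrix(stats::rnorm(nPerBlob * d, 0, sd), nPerBlob, d) +
      matrix(centers[b, ], nPerBlob, d, byrow = TRUE)))
  list(coords = coords,
       labels = rep(seq_len(nrow(centers)), each = nPerBlob))
}

# brute-force k nearest neighbours (independent of the package's search)
bruteKnn <- function(coords, k) {
  n <- nrow(coords)
  d <- as.matrix(dist(coords))
  t(vapply(seq_len(n), function(i) {
    d[i, i] <- Inf
    order(d[i, ], seq_len(n))[seq_len(k)]
  }, integer(k)))
}

edgeSet <- function(g) {
  el <- igraph::as_edgelist(g, names = FALSE)
  sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
}

# brute-force pair-counting adjusted Rand index
ariPairCounting <- function(a, b) {
  n <- length(a)
  pairs <- utils::combn(n, 2)
  sa <- a[pairs[1, ]] == a[pairs[2, ]]
  sb <- b[pairs[1, ]] == b[pairs[2, ]]
  n11 <- sum(sa & sb); n00 <- sum(!sa & !sb)
  n10 <- sum(sa & !sb); n01 <- sum(!sa & sb)
  np <- ncol(pairs)
  expected <- (n11 + n10) * (n11 + n01) / np
  maxidx <- ((n11 + n10) + (n11 + n01)) / 2
  if (maxidx == expected) return(0)
  (n11 - expected) / (maxidx - expected)
}

# all set partitions of 1..n (restricted-growth strings)
allPartitions <- function(n) {
  out <- list()
  rec <- function(code, maxv) {
    if (length(code) == n) { out[[length(out) + 1L]] <<- code; return() }
    for (v in seq_len(maxv + 1L)) rec(c(code, v), max(maxv, v))
  }
  rec(integer(0), 0L)
  out
}

# expand a weighted sample into a classical one (integer multiplicities)
expandRows <- function(x, w) {
  x <- as.matrix(x)
  x[rep(seq_len(nrow(x)), times = w), , drop = FALSE]
}

# does partition `fine` refine partition `coarse`? (every fine group
# contained in exactly one coarse group)
isRefinement <- function(fine, coarse) {
  all(vapply(split(coarse, fine),
             function(g) length(unique(g)) == 1L, logical(1)))
}

# small log-normalized expression fixture with dimnames
makeExprFixture <- function(nGenes = 30, nCells = 50, seed = 11) {
  set.seed(seed)
  m <- matrix(round(stats::rexp(nGenes * nCells, 1), 3), nGenes, nCells,
              dimnames = list(sprintf("g%03d", seq_len(nGenes)),
                              sprintf("c%03d", seq_len(nCells))))
  m
}

randomPartition <- function(n, k, seed) {
  set.seed(seed)
  memb <- sample.int(k, n, replace = TRUE)
  memb[sample.int(n, k)] <- seq_len(k)  # guarantee non-empty
  MetacellPartition(memb)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
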