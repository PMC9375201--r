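twoCliqueGraph <- function(size = 10) {
  g <- igraph::disjoint_union(igraph::make_full_graph(size),
                          igraph::make_full_graph(size))
  igraph::add_edges(g, c(1, size + 1))
}

test_that("walktrap dendrogram respects connected components", {
  g <- igraph::disjoint_union(igraph::make_full_graph(3),
                              igraph::make_full_graph(3))
  tree <- walktrapDendrogram(g)
  expect_equal(length(tree@communities), 2L)
  expect_equal(nrow(tree@communities[[1]]$merges), 2L)  # 3 nodes -> 2 merges
  # complete graph on 4 nodes: cutting at 1 community keeps all together
  k4 <- walktrapDendrogram(igraph::make_full_graph(4))
  p <- cutToMetacells(k4, nMetacells = 1)
  expect_equal(nMetacells(p), 1L)
  expect_equal(mcSizes(p), 4L)
  expect_error(walktrapDendrogram(igraph::make_empty_graph(0)),
               "at least one node")
})

test_that("two cliques joined by one edge are recovered at a 2-cut", {
  g <- twoCliqueGraph(10)
  p <- cutToMetacells(walktrapDendrogram(g), nMetacells = 2)
  expect_equal(membership(p), rep(c(1L, 2L), each = 10))
})

test_that("cutToMetacells honours gamma, components and bounds", {
  g <- twoCliqueGraph(10)
  tree <- walktrapDendrogram(g)
  p1 <- cutToMetacells(tree, gamma = 1)
  expect_equal(membership(p1), 1:20)   # identity partition
  expect_equal(gammaLevel(p1), 1)
  p4 <- cutToMetacells(tree, gamma = 5)
  expect_equal(nMetacells(p4), 4L)
  expect_equal(sum(mcSizes(p4)), 20L)  # conservation
  # disconnected graph: can't have fewer metacells than components
  g2 <- igraph::disjoint_union(igraph::make_full_graph(3),
                              igraph::make_full_graph(3))
  t2 <- walktrapDendrogram(g2)
  expect_error(cutToMetacells(t2, nMetacells = 1), "components")
  expect_error(cutToMetacells(t2, nMetacells = 7), "exceeds")
  expect_error(cutToMetacells(t2), "exactly one")
  # gamma path clamps to the component count instead of erroring
  expect_equal(nMetacells(cutToMetacells(t2, gamma = 6)), 2L)
})

test_that("finer cuts refine coarser cuts of the same dendrogram", {
  blobs <- makeBlobs(40, rbind(c(0, 0), c(12, 0), c(0, 12)), seed = 21)
  g <- buildCellGraph(blobs$coords, k = 5)
  tree <- walktrapDendrogram(g)
  cuts <- lapply(c(3, 6, 12, 24, 60), function(k)
    membership(cutToMetacells(tree, nMetacells = k)))
  for (i in seq_len(length(cuts) - 1))
    expect_true(isRefinement(cuts[[i + 1]], cuts[[i]]))
})

test_that("cut allocation across components is proportional and monotone", {
  # components of sizes 12, 6, 3: allocation must track sizes
  sizes <- c(12L, 6L, 3L)
  a <- metagrain:::allocateAcrossComponents(sizes, 7)
  expect_equal(sum(a), 7)
  expect_true(all(a >= 1) && all(a <= sizes))
  expect_equal(a, c(4L, 2L, 1L))
  prev <- metagrain:::allocateAcrossComponents(sizes, 3)
  for (total in 4:21) {
    cur <- metagrain:::allocateAcrossComponents(sizes, total)
    expect_true(all(cur >= prev))  # house monotonicity
    prev <- cur
  }
})

test_that("two separated blobs coarse-grain into pure metacells", {
  blobs <- makeBlobs(50, rbind(c(0, 0), c(15, 0)), sd = 1, seed = 8)
  g <- buildCellGraph(blobs$coords, k = 5)
  p <- cutToMetacells(walktrapDendrogram(g), gamma = 10)
  expect_equal(nMetacells(p), 10L)
  pu <- purity(p, blobs$labels)
  expect_equal(pu$values, rep(1, 10))  # no metacell spans both blobs
})

test_that("louvain backend matches the requested graining level", {
  g <- twoCliqueGraph(8)
  p1 <- louvainPartition(g, gamma = 1)
  expect_equal(membership(p1), 1:16)
  set.seed(1)
  pk <- louvainPartition(igraph::make_full_graph(12), gamma = 12)
  expect_equal(nMetacells(pk), 1L)
  expect_identical(pk@algorithm, "louvain")
  # two-blob geometry: purity comparable to walktrap
  blobs <- makeBlobs(100, rbind(c(0, 0), c(15, 0)), sd = 1, seed = 13)
  gg <- buildCellGraph(blobs$coords, k = 5)
  set.seed(2)
  pl <- louvainPartition(gg, gamma = 10)
  pw <- cutToMetacells(walktrapDendrogram(gg), gamma = 10)
  expect_equal(nMetacells(pl), 20L)
  expect_gte(purity(pl, blobs$labels)$median,
             purity(pw, blobs$labels)$median - 0.1)
})

test_that("gammaForSample follows the capped integer-part formula", {
  expect_equal(gammaForSample(150), 7L)
  expect_equal(gammaForSample(1000), 10L)
  expect_equal(gammaForSample(200), 10L)
  expect_equal(gammaForSample(19), 1L)  # clamped, formula would give 0
  expect_equal(gammaForSample(1), 1L)
})

test_that("approximate coarse-graining degenerates to the exact pipeline", {
  sim <- simulateCounts(nCells = 300, nGenes = 120, nTypes = 3, seed = 31)
  expr <- normalizeLog(sim$counts)
  exact <- coarseGrain(expr, gamma = 10, nHVG = 60)$partition
  approx <- approximateCoarseGrain(expr, gamma = 10, nSubsample = 300,
                                   seed = 99, nHVG = 60)
  expect_equal(membership(approx), membership(exact))
  expect_error(approximateCoarseGrain(expr, gamma = 10, nSubsample = 20,
                                      seed = 1), "below the requested")
})

test_that("cells identical to a subsampled cell join that cell's metacell", {
  blobs <- makeBlobs(30, rbind(c(0, 0), c(40, 0)), sd = 0.5, seed = 41)
  # duplicate the coordinates as 'genes' so expression == geometry
  expr <- t(cbind(blobs$coords, blobs$coords, blobs$coords))
  rownames(expr) <- paste0("g", 1:6)
  dup <- cbind(expr, expr[, 1])  # cell 61 duplicates cell 1
  colnames(dup) <- paste0("c", 1:61)
  set.seed(5)
  p <- approximateCoarseGrain(dup, gamma = 6, nSubsample = 60, seed = 17,
                              nHVG = 6, nPCs = 2, k = 5)
  expect_equal(membership(p)[61], membership(p)[1])
})

test_that("splitByAnnotation yields pure metacells and refines the input", {
  p <- MetacellPartition(c(1, 1, 1, 2, 2))
  labs <- c("A", "A", "B", "B", "B")
  sp <- splitByAnnotation(p, labs)
  expect_equal(membership(sp), c(1L, 1L, 2L, 3L, 3L))
  expect_true(isRefinement(membership(sp), membership(p)))
  expect_equal(purity(sp, labs)$values, rep(1, 3))
  # already-pure partitions are a fixed point (up to relabeling)
  expect_equal(membership(splitByAnnotation(sp, labs)), membership(sp))
  expect_error(splitByAnnotation(p, c("A", NA, "B", "B", "B")), "every cell")
  # property: random partitions with random labels end up pure
  for (s in 1:3) {
    part <- randomPartition(60, 8, seed = s)
    set.seed(s + 100)
    labs2 <- sample(letters[1:3], 60, replace = TRUE)
    sp2 <- splitByAnnotation(part, labs2)
    expect_equal(purity(sp2, labs2)$values,
                 rep(1, nMetacells(sp2)))
    expect_true(isRefinement(membership(sp2), membership(part)))
  }
})

test_that("metacell network counts inter-metacell edges exactly", {
  g <- igraph::make_graph(c(1, 2, 2, 3, 3, 4), directed = FALSE)
  p <- MetacellPartition(c(1, 1, 2, 2))
  mg <- metacellNetwork(g, p)
  expect_equal(igraph::ecount(mg), 1L)
  expect_equal(igraph::E(mg)$weight, 1L)
  # gamma = 1: network is the single-cell graph with unit weights
  pid <- MetacellPartition(1:4)
  mgi <- metacellNetwork(g, pid)
  expect_equal(edgeSet(mgi), edgeSet(g))
  expect_true(all(igraph::E(mgi)$weight == 1L))
  # brute-force oracle on a random graph and partition
  set.seed(6)
  gr <- igraph::sample_gnp(30, 0.2)
  part <- randomPartition(30, 5, seed = 7)
  mgr <- metacellNetwork(gr, part)
  el <- igraph::as_edgelist(gr, names = FALSE)
  memb <- membership(part)
  for (e in seq_len(igraph::ecount(mgr))) {
    ends <- igraph::ends(mgr, e)
    cnt <- sum((memb[el[, 1]] == ends[1] & memb[el[, 2]] == ends[2]) |
               (memb[el[, 1]] == ends[2] & memb[el[, 2]] == ends[1]))
    expect_equal(igraph::E(mgr)$weight[e], cnt)
  }
  expect_error(metacellNetwork(g, MetacellPartition(c(1, 1, 2))),
               "same cells")
})
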