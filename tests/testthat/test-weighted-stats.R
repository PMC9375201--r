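# The module's central correctness property: with unit weights every
# statistic reduces to its classical counterpart, and with integer weights
# it equals the classical statistic on the multiplicity-expanded sample.

test_that("weightedScale reduces to classical z-scoring at unit weights", {
  set.seed(1)
  m <- matrix(rnorm(8 * 5), 8, 5)
  ws <- weightedScale(m, rep(1, 8))
  expect_equal(unname(ws), unname(scale(m)), tolerance = 1e-10,
               ignore_attr = TRUE)
  # constant gene -> zeros
  m[, 2] <- 7
  expect_equal(weightedScale(m, rep(1, 8))[, 2], rep(0, 8))
})

test_that("weightedScale equals z-scoring of the expanded sample", {
  x <- matrix(c(1, 2, 3, 0.5, -1, 2), ncol = 2)
  w <- c(2L, 1L, 1L)
  ws <- weightedScale(x, w)
  ref <- scale(expandRows(x, w))
  expect_equal(unname(ws), unname(ref[c(1, 3, 4), ]), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("weightedPCA reduces to standard PCA at equal weights", {
  set.seed(2)
  m <- matrix(rnorm(12 * 7), 12, 7)
  emb <- weightedPCA(m, rep(1, 12), nComponents = 4)
  ref <- prcomp(scale(m))$x[, 1:4]
  for (j in 1:4)
    expect_lt(min(max(abs(emb@coords[, j] - ref[, j])),
                  max(abs(emb@coords[, j] + ref[, j]))), 1e-8)
  # rank-1 input: a single non-zero singular value
  r1 <- outer(1:6, c(1, -2, 0.5))
  e1 <- weightedPCA(r1, rep(1, 6), nComponents = 2, scale = FALSE)
  expect_gt(e1@singular[1], 1e-8)
  expect_lt(e1@singular[2] / e1@singular[1], 1e-10)
  expect_error(weightedPCA(m, rep(1, 12), nComponents = 7), "nComponents")
})

test_that("weightedPCA matches PCA of the multiplicity-expanded matrix", {
  set.seed(3)
  m <- matrix(rnorm(30 * 15), 30, 15)
  w <- sample(1:4, 30, replace = TRUE)
  emb <- weightedPCA(m, w, nComponents = 5)
  exp <- expandRows(m, w)
  refAll <- prcomp(scale(exp))$x[, 1:5]
  ref <- refAll[cumsum(w) - w + 1, ]  # first copy of each metacell
  for (j in 1:5)
    expect_lt(min(max(abs(emb@coords[, j] - ref[, j])),
                  max(abs(emb@coords[, j] + ref[, j]))), 1e-6)
})

test_that("weightedHclust reduces to Ward and matches the expanded tree", {
  set.seed(4)
  pts <- matrix(rnorm(20 * 3), 20, 3)
  lab <- weightedHclust(pts, rep(1, 20), nClusters = 4)
  ref <- cutree(hclust(dist(pts)^2, method = "ward.D"), 4)
  expect_equal(adjustedRandIndex(lab, ref), 1)
  # two far-apart groups are recovered
  grp <- rbind(matrix(rnorm(10 * 2), 10, 2),
               matrix(rnorm(8 * 2) + 50, 8, 2))
  expect_equal(unname(as.vector(weightedHclust(grp, rep(1, 18), 2))),
               rep(c(1L, 2L), c(10, 8)))
  expect_error(weightedHclust(pts, rep(1, 20), 25), "out of range")
})

test_that("integer-weight Ward equals Ward on duplicated points", {
  for (s in 1:3) {
    set.seed(s)
    pts <- matrix(rnorm(12 * 2), 12, 2)
    w <- sample(1:3, 12, replace = TRUE)
    lab <- weightedHclust(pts, w, nClusters = 4)
    expTree <- hclust(dist(expandRows(pts, w))^2, method = "ward.D")
    refExpanded <- cutree(expTree, 4)
    ref <- refExpanded[cumsum(w) - w + 1]
    expect_equal(adjustedRandIndex(lab, ref), 1)
  }
})

test_that("weightedSilhouette reduces to the classical silhouette", {
  skip_if_not_installed("cluster")
  set.seed(5)
  pts <- rbind(matrix(rnorm(14), 7, 2), matrix(rnorm(14) + 4, 7, 2))
  lab <- rep(1:2, each = 7)
  ws <- weightedSilhouette(pts, lab, rep(1, 14))
  ref <- cluster::silhouette(lab, dist(pts))
  expect_equal(ws@s, unname(ref[, "sil_width"]), tolerance = 1e-10)
  expect_equal(ws@S, mean(ref[, "sil_width"]), tolerance = 1e-10)
  expect_true(all(ws@s >= -1 & ws@s <= 1))
  expect_error(weightedSilhouette(pts, rep(1, 14)), "2 clusters")
})

test_that("weightedSilhouette matches hand-computed weighted formulas", {
  # 3 metacells, weights (2, 1, 1), 1-D positions 0, 1, 5
  pts <- matrix(c(0, 1, 5), ncol = 1)
  w <- c(2, 1, 1)
  lab <- c(1, 1, 2)
  ws <- weightedSilhouette(pts, lab, w)
  # metacell 1: a = d(1,2)*1 / (|C1| - 2) = 1; b = d(1,3)*1/1 = 5
  expect_equal(ws@s[1], (5 - 1) / 5)
  # metacell 2: a = d(2,1)*2 / (3 - 1) = 1; b = d(2,3) = 4
  expect_equal(ws@s[2], (4 - 1) / 4)
  # metacell 3 is alone in its cluster -> 0
  expect_equal(ws@s[3], 0)
  expect_equal(ws@S, (2 * 0.8 + 1 * 0.75 + 0) / 4)
  # a singleton *metacell* cluster with size > 1 is also defined as 0
  ws2 <- weightedSilhouette(pts, c(1, 2, 2), c(3, 1, 1))
  expect_equal(ws2@s[1], 0)
})

test_that("weightedTTest reduces to Welch's t-test at unit weights", {
  set.seed(6)
  x <- rnorm(9); y <- rnorm(11, 0.5)
  r <- weightedTTest(x, y)
  ref <- t.test(x, y)
  expect_equal(r$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(r$df, unname(ref$parameter), tolerance = 1e-12)
  expect_equal(r$p, ref$p.value, tolerance = 1e-12)
  expect_equal(r$logFC, mean(x) - mean(y), tolerance = 1e-12)
  # identical groups: t = 0, p = 1 (also when both variances are zero)
  expect_equal(weightedTTest(c(1, 1), c(1, 1))[c("t", "p")],
               list(t = 0, p = 1))
  r0 <- weightedTTest(rep(2, 3), rep(1, 3))
  expect_equal(r0$p, 0)
  expect_error(weightedTTest(1, c(1, 2)), "weight >= 2")
})

test_that("weightedTTest equals Welch's test on the expanded samples", {
  set.seed(7)
  x <- rnorm(5); y <- rnorm(6, 1)
  wx <- sample(1:4, 5, TRUE); wy <- sample(1:4, 6, TRUE)
  r <- weightedTTest(x, y, wx, wy)
  ref <- t.test(rep(x, wx), rep(y, wy))
  expect_equal(r$t, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(r$df, unname(ref$parameter), tolerance = 1e-9)
  expect_equal(r$p, ref$p.value, tolerance = 1e-9)
})

test_that("weightedPearson reduces to and expands from classical Pearson", {
  set.seed(8)
  x <- rnorm(20); y <- x + rnorm(20)
  r <- weightedPearson(x, y)
  ref <- cor.test(x, y)
  expect_equal(r$estimate, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(r$p, ref$p.value, tolerance = 1e-12)
  expect_equal(weightedPearson(x, x)$estimate, 1)
  w <- sample(1:3, 20, TRUE)
  rw <- weightedPearson(x, y, w)
  refw <- cor.test(rep(x, w), rep(y, w))
  expect_equal(rw$estimate, unname(refw$estimate), tolerance = 1e-12)
  expect_equal(rw$p, refw$p.value, tolerance = 1e-10)
})

test_that("weightedDE ranks an exclusively-expressed gene first", {
  m <- matrix(0.1, 10, 12,
              dimnames = list(NULL, sprintf("gene%02d", 1:12)))
  m[1:5, 1] <- 5  # gene01 expressed only in group A metacells
  set.seed(9)
  m[, 2:12] <- m[, 2:12] + matrix(rnorm(10 * 11, 0, 0.01), 10)
  de <- weightedDE(m, rep(c("A", "B"), each = 5), rep(2, 10))
  deA <- de[de$group == "A", ]
  expect_equal(deA$gene[deA$rank == 1], "gene01")
  expect_true(all(de$p_adj >= de$p))
  # BH monotone in p rank
  o <- order(deA$p)
  expect_true(all(diff(deA$p_adj[o]) >= -1e-15))
})

test_that("weightedDE with unit weights matches per-gene Welch tests", {
  set.seed(10)
  m <- matrix(rnorm(16 * 6), 16, 6,
              dimnames = list(NULL, paste0("g", 1:6)))
  lab <- rep(c("A", "B"), each = 8)
  de <- weightedDE(m, lab, rep(1, 16))
  deA <- de[de$group == "A", ]
  for (j in 1:6) {
    ref <- t.test(m[lab == "A", j], m[lab == "B", j])
    expect_equal(deA$t[j], unname(ref$statistic), tolerance = 1e-9)
    expect_equal(deA$p[j], ref$p.value, tolerance = 1e-9)
  }
})

test_that("weightedDE controls false positives on null data", {
  # no true effects, permuted single-cell labels, unit weights: the test
  # must be calibrated (BH discoveries stay below 10% of genes)
  sim <- simulateCounts(nCells = 400, nGenes = 200, nTypes = 2,
                        effectLfc = 0, seed = 14)
  expr <- normalizeLog(sim$counts)
  set.seed(15)
  groups <- sample(as.character(sim$labels))
  de <- weightedDE(t(as.matrix(expr)), groups, rep(1, 400))
  expect_lt(mean(de$p_adj < 0.05), 0.10)
  hist <- table(cut(de$p, seq(0, 1, 0.25)))
  expect_gt(min(hist) / max(hist), 0.5)  # uniform-ish p distribution
})

test_that("signatureScore sums max-normalized marker expression", {
  m <- rbind(g1 = c(2, 4), g2 = c(1, 1), g3 = c(0, 3))
  colnames(m) <- c("c1", "c2")
  expect_equal(signatureScore(m, "g1"), c(c1 = 0.5, c2 = 1))
  expect_equal(signatureScore(m, c("g1", "g3")), c(c1 = 0.5, c2 = 2))
  expect_warning(s <- signatureScore(m, c("g1", "absent")), "skipped")
  expect_equal(s, c(c1 = 0.5, c2 = 1))
  expect_error(signatureScore(m, "nope"), "no signature gene")
  # hand formula on a 5-gene signature
  set.seed(11)
  mm <- matrix(runif(5 * 4), 5, 4,
               dimnames = list(paste0("g", 1:5), paste0("c", 1:4)))
  ref <- colSums(mm / apply(mm, 1, max))
  expect_equal(signatureScore(mm, paste0("g", 1:5)), ref, tolerance = 1e-12)
})

test_that("scoreAUC behaves as a rank statistic", {
  expect_equal(scoreAUC(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE)), 1)
  s <- c(0.9, 0.8, 0.4, 0.3, 0.7)
  l <- c(TRUE, FALSE, TRUE, FALSE, TRUE)
  expect_equal(scoreAUC(-s, l), 1 - scoreAUC(s, l))
  # independent scores -> around 0.5
  set.seed(12)
  expect_equal(scoreAUC(rnorm(2000), rbinom(2000, 1, 0.5)), 0.5,
               tolerance = 0.05)
  # weights replicate observations
  set.seed(13)
  sc <- rnorm(15); lb <- rbinom(15, 1, 0.5) == 1
  w <- sample(1:3, 15, TRUE)
  expect_equal(scoreAUC(sc, lb, w),
               scoreAUC(rep(sc, w), rep(lb, w)), tolerance = 1e-12)
})
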