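# The scaled-down simulation study shared by the acceptance checks:
# DE-recovery and dropout-rescue computations on simulated populations.

# TPR of metacell-level DE recovery vs the single-cell reference set,
# plus the subsampling baseline at matched size
deRecoveryStudy <- function(sim, gamma = 10, lfcThr = 0.5,
                            subseed = 1) {
  expr <- normalizeLog(sim$counts)
  labs <- as.character(sim$labels)
  scDE <- weightedDE(t(as.matrix(expr)), labs, rep(1, ncol(expr)))
  M <- deReferenceSet(scDE, lfcThr = lfcThr)
  cg <- coarseGrain(expr, gamma = gamma)
  prof <- averageExpression(expr, cg$partition)
  mcLab <- majorityAnnotation(cg$partition, labs)
  mcDE <- weightedDE(prof, mcLab)
  tprMC <- tpr(M, deRecoveredSet(mcDE, length(M)))
  set.seed(subseed)
  keep <- sort(sample.int(ncol(expr), round(ncol(expr) / gamma)))
  subDE <- weightedDE(t(as.matrix(expr[, keep])), labs[keep],
                      rep(1, length(keep)))
  tprSub <- tpr(M, deRecoveredSet(subDE, length(M)))
  list(tprMC = tprMC, tprSub = tprSub, sizeM = length(M))
}

# mean detected fraction of each type's true markers, in single cells of
# that type and in metacells annotated to it
markerDetection <- function(sim, gamma = 20) {
  expr <- normalizeLog(sim$counts)
  labs <- as.character(sim$labels)
  cg <- coarseGrain(expr, gamma = gamma)
  prof <- as.matrix(SummarizedExperiment::assay(
    averageExpression(expr, cg$partition), "mean"))
  mcLab <- majorityAnnotation(cg$partition, labs)
  types <- names(sim$trueDE)
  sc <- mc <- numeric(length(types))
  names(sc) <- names(mc) <- types
  for (ty in types) {
    g <- sim$trueDE[[ty]]
    sc[ty] <- mean(as.matrix(expr[g, labs == ty, drop = FALSE]) > 0)
    mc[ty] <- mean(prof[g, mcLab == ty, drop = FALSE] > 0)
  }
  list(singleCell = sc, metacell = mc)
}
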