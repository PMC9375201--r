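---
title: "Metacell coarse-graining: model, conventions and design choices"
author: "metagrain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metacell coarse-graining: model, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metagrain)
```

## The coarse-graining model

Single-cell RNA-seq datasets carry heavy redundancy: many cells are
transcriptomic near-replicates of each other. `metagrain` merges such
cells into *metacells* and gives every downstream statistic a weight equal
to the number of cells a metacell contains, so that analyses on the
reduced data approximate the analyses one would have run on the full
matrix.

The construction is:

1. **Feature selection.** The `nHVG` most variable genes of the
   log-normalized matrix (`normalizeLog`: counts scaled to a common
   library size, then `log(1 + x)`).
2. **Embedding.** PCA on the selected genes (`embedPCA`), genes centered
   across cells. `nPCs = 10` components by default.
3. **Graph.** A k-nearest-neighbour graph in PCA space (`buildCellGraph`,
   `k = 5` by default, Euclidean distance, directed lists symmetrized by
   union). A shared-nearest-neighbour variant prunes edges whose
   neighbour-list Jaccard overlap is below 1/15.
4. **Communities.** Walktrap (short random walks, walk length 4)
   produces an agglomerative merge hierarchy per connected component
   (`walktrapDendrogram`). Louvain is available as an alternative backend
   (`louvainPartition`).
5. **Cut.** The hierarchy is cut so that exactly
   `N_mc = round(N_c / gamma)` metacells remain (`cutToMetacells`). The
   *graining level* `gamma` is the ratio of cells to metacells; `gamma = 1`
   is the identity. Because the hierarchy is stored, other graining
   levels can be explored without recomputing the random walks.

A metacell's expression profile is the arithmetic mean of its members'
log-normalized expression (`averageExpression`); auxiliary layers
(spliced/unspliced counts for RNA velocity) and per-cell embeddings are
averaged the same way. Mass is conserved: the size-weighted sum of
metacell means equals the per-gene sum over cells, to machine precision.

### Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `gamma` | 10 | cells per metacell; useful range roughly 10–50 |
| `k` | 5 | kNN neighbourhood size |
| `nPCs` | 10 | PCA components for the graph |
| `nHVG` | 1000 | variable genes used for the construction |
| `steps` | 4 | walktrap walk length (the algorithm's canonical default) |

For per-sample coarse-graining in multi-sample integration,
`gammaForSample(n) = min(floor(n / 20), 10)`, clamped below at 1, keeps
at least about 20 metacells per sample.

## Sample-weighted statistics

Every statistic treats metacell `i` as `size(i)` observations located at
its profile. Two properties pin down all conventions and serve as the
test suite's central oracles:

* **Reduction**: with all weights 1, each statistic equals its classical
  counterpart.
* **Expansion**: with integer weights, each statistic equals the
  classical one computed on the sample in which row `i` is repeated
  `size(i)` times.

Concretely (`w` the sizes, `N_c = sum(w)`):

* `weightedScale` — centre at `mu = sum(w x) / N_c`, divide by the
  frequency-weight standard deviation
  `sqrt(sum(w (x - mu)^2) / (N_c - 1))`. We deliberately use the
  frequency-weight normalisation rather than the normalized-weight
  correction `1 / (1 - sum((w/N_c)^2))` found in some weighted-scaling
  implementations: only the frequency convention satisfies the expansion
  property above.
* `weightedPCA` — SVD of the weighted covariance
  `(1/N_c) t(X) W X` of the scaled matrix `X`; the embedding is `X V`.
  Component signs are fixed (largest-magnitude loading positive) so
  results are deterministic.
* `weightedHclust` — Ward agglomeration where each metacell enters as a
  pre-formed group of `size(i)` points at its centroid. `stats::hclust`
  with `members = w` applies the correct Lance–Williams counts, but the
  *initial* dissimilarities must also be the exact Ward merge costs
  `2 w_i w_j / (w_i + w_j) * ||c_i - c_j||^2`; passing plain Euclidean
  distances breaks the equivalence with the expanded point set (the
  Lance–Williams updates diverge after the zero-height duplicate
  merges). With the exact initialisation the weighted tree is identical
  to Ward on the duplicated points.
* `weightedSilhouette` — the within-distance
  `a(i) = sum_{j in C, j != i} d(i,j) size(j) / (|C| - size(i))` and
  between-distance `b(i) = min_k sum_{j in C_k} d(i,j) size(j) / |C_k|`,
  with `|C|` counting cells, `s(i) = (b - a) / max(a, b)` and the overall
  `S = sum(s size) / N_c`. A cluster holding a single metacell has
  `a(i)` undefined (`|C| - size(i) = 0`); we define `s(i) = 0` there,
  which also covers the classical singleton rule.
* `weightedTTest` — Welch's unequal-variance test in the frequency-weight
  convention (`n = sum(w)`, variance denominator `sum(w) - 1`,
  Welch–Satterthwaite degrees of freedom). Welch rather than a pooled
  variance is the safer default when cluster sizes and spreads differ.
  `logFC` is the difference of weighted means in log space.
* `weightedDE` — one-vs-rest `weightedTTest` per gene with
  Benjamini–Hochberg adjustment within each comparison.
* `weightedPearson` — correlation from normalized-weight covariances,
  p-value from the `t = rho sqrt((sum(w) - 2) / (1 - rho^2))`
  approximation.
* `signatureScore` / `scoreAUC` — sum of max-normalized marker
  expression; rank AUC in which a metacell counts `size(i)` times.

### A calibration caveat (pseudo-replication)

Treating a metacell as `size(i)` independent cells understates the
variance of group means when the grouping is unrelated to the averaging:
averaging `gamma` noisy cells shrinks the spread of metacell values by
about `gamma`, so under a *random* regrouping of structureless data the
weighted t statistic is inflated by roughly `sqrt(gamma)`. The test is
therefore calibrated at the single-cell level (unit weights, where the
suite verifies a < 10% false-positive rate with uniform p-values under
permuted labels) but should be read as a ranking device, not a
calibrated test, at `gamma > 1`. This mirrors how the recovery metric is
defined: the metacell DE list is compared against the single-cell
reference set by the true-positive rate of equal-sized sets.

## Evaluation metrics

* `purity` — majority-type fraction per metacell (median reported);
  `rareTypePurity` weights the purity of metacells annotated to a rare
  type by the number of rare cells they contain.
* `adjustedRandIndex` — Hubert–Arabie ARI from the contingency table,
  verified exhaustively against pair counting on all 203 partitions of 6
  elements.
* `deReferenceSet` / `deRecoveredSet` / `tpr` — the single-cell set `M`
  (union over clusters of significantly upregulated genes, BH-adjusted
  p < 0.05 and logFC above a dataset-dependent threshold, 0.5 by
  default) versus the equal-sized metacell list (top `|M|` significant
  upregulated genes by logFC; a gene significant in several clusters
  keeps its largest logFC). `TPR = |M ∩ M~| / |M|`.
* `goMatchScoreRatio` — after filtering to genes expressed (> 0) in more
  than half of the cells, all gene pairs are ranked by correlation at
  each level (classical at single-cell, size-weighted at metacell); the
  mean GO-set Jaccard of metacell-exclusive top pairs over that of
  single-cell-exclusive pairs measures whether coarse-graining surfaces
  more functionally related pairs. Pairs are ranked by signed
  correlation (a magnitude option exists).
* `velocityPurity` — `max_x median_y cos(v(x), v(y))` within each
  metacell; the cosine with a zero vector is 0, a singleton metacell
  scores 1, and even-count medians use the midpoint convention.
  `velocitySimilarity` is the median cosine between each cell's vector
  and its metacell's vector; a subsampling baseline matches each cell to
  its nearest retained cell instead.

## Partition machinery details

* **Cut allocation across components.** On disconnected graphs the
  requested metacell count is distributed across components
  proportionally to their sizes with a floor of one. We use a
  highest-averages (D'Hondt) rule rather than largest-remainder because
  it is *house monotone*: raising the total never lowers any component's
  share, so cutting the same hierarchy at a finer level always refines
  the coarser partition — a property the test suite checks directly.
  Ties go to the larger component, then the lower index.
* **Louvain graining control.** Louvain does not expose a community
  count; oversized communities are re-partitioned recursively (Louvain
  on the induced subgraph, walktrap 2-cut when Louvain refuses to
  split), taking the split that adds fewest communities first, and any
  overshoot is corrected by merging the pair with the heaviest
  connecting edge weight.
* **Approximate mode** (`approximateCoarseGrain`). For very large
  datasets the exact pipeline runs on a seeded uniform subsample
  targeting the full-data metacell count; remaining cells are projected
  into the subsample's PCA basis and assigned to the nearest metacell
  centroid (the centroid is our choice of the metacell's representative
  point). With the subsample equal to the full dataset the result is
  bit-identical to the exact pipeline.
* **Annotation-consistent metacells.** `splitByAnnotation` splits any
  metacell spanning several annotation categories, so the result is
  pure by construction and always refines its input.
* **Determinism.** Distance and ranking ties break by lower index or
  lexicographic label; metacell ids are renumbered by first member cell;
  no randomness is used outside explicitly seeded operations
  (subsampling, simulation, Louvain's internal ordering).

## What the synthetic data emulates — and what it does not

`simulateCounts` draws negative-binomial counts (dispersion 0.5, typical
scRNA-seq overdispersion) for a population of discrete types sharing a
baseline log-normal expression program; each type up-shifts a fraction
`deFrac` of genes by `effectLfc` (log2), cells get uniform library sizes
in 1500–3000, and independent Bernoulli dropout thins the counts. The
package's own evaluation uses 2000 cells x 500 genes, 5 types, 20
markers per type at a 4-fold change, 10% baseline dropout (70% in the
dropout-rescue study) — sizes chosen so the whole study runs on a
laptop-scale budget; they are stated here as the package's evaluation
conditions. `simulateVelocity` points each type's cells toward the next
type's centroid plus Gaussian noise, emulating a directed
differentiation flow; `simulateGO` gives module genes shared term
blocks.

These generators produce well-separated spherical populations with
independent noise. They do not emulate batch effects, continuous
trajectories within types, gene–gene correlation beyond type structure,
ampliation biases, or realistic splice kinetics. Passing the suite
therefore demonstrates correctness of the algorithms and exact weighted
statistics, and structure preservation under the stated conditions — not
performance on arbitrary real tissues.

## Numerical choices and degenerate inputs

* PCA uses the dense SVD; at the package's problem sizes a truncated
  solver is unnecessary, and basis orthonormality is validated at 1e-8.
* Zero-variance genes scale to 0 rather than NaN; zero-total cells are
  a hard error naming the cell; `t = 0, p = 1` when both groups are
  constant and equal, `p = 0` when constant and different.
* An sNN cell isolated by pruning is re-attached to its nearest
  neighbour so graphs never contain degree-0 nodes.
* `deRecoveredSet` records a shortfall attribute instead of failing when
  fewer significant genes exist than requested; an empty reference set
  is an error because the recovery rate is undefined.
* On-disk metacell ids are 0-based (TSV convention); in-memory ids are
  1-based contiguous integers.

## Known limitations

* The weighted t-test is anti-conservative under random regrouping at
  `gamma > 1` (see the caveat above).
* Exact nearest-neighbour search is quadratic in cell number; beyond
  ~10^5 cells use `approximateCoarseGrain`.
* Velocity vectors are consumed, not estimated; spliced/unspliced layer
  averaging prepares inputs for an external velocity estimator.
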