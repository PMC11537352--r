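---
title: "Benchmarking HV and SV gene sets for cell-type clustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking HV and SV gene sets for cell-type clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svhvbench)
```

## The question the package answers

Spatial transcriptomics assays deliver a cells-by-genes count matrix
together with the position of every cell or spot in the tissue. Two
families of informative genes are routinely extracted before
clustering:

* **Highly variable (HV) genes** vary across cells more than expected
  at their mean expression, irrespective of position. They are the
  conventional feature set for cell-type clustering.
* **Spatially variable (SV) genes** show spatial autocorrelation over
  the tissue coordinates and are typically used to define spatial
  domains.

The two sets overlap but are far from identical: a marker of a
spatially dispersed immune cell type is highly variable but not
spatially variable, while a gene tracking a morphogen gradient is
spatially variable yet may add little cell-type information. This
package provides a reusable pipeline for asking, on any dataset with
ground-truth labels, whether clustering on the **union** of the two
sets beats either set alone, and for quantifying the answer with both
conventional and spatially adjusted metrics.

## Pipeline

For each dataset and each gene set (`hv`, `sv`, `union`, `all`):

1. **Preprocess** (`preprocess_pipeline()`): genes and cells whose mean
   expression falls outside the Tukey fences (quartiles ± 1.5 IQR) of
   the respective mean distribution are removed (genes first, then
   cells); cell types holding strictly less than 5% of cells are
   dropped (frequencies evaluated once, a class at exactly 5% is
   kept). Normalization is either analytic Pearson residuals
   (`(x - mu)/sqrt(mu + mu^2/theta)` under the offset
   negative-binomial null with `theta = 100`, clipped to
   `±sqrt(n_cells)`) or, for imaging platforms, rescaling by 1000
   followed by log-normalization to the median cell total.
2. **Select genes**: HV by Pearson-residual variance (> 1 defines
   candidacy) or by the LOESS excess of the coefficient of variation
   over its log-mean trend (> 0 defines candidacy); the low / medium /
   high levels keep candidates at or above the 50th / 70th / 90th
   percentile of the candidate statistics. SV from a per-gene p-value
   table (an external detector such as SPARK) or from the built-in
   Moran's I permutation scorer; low keeps `p < 0.05`, medium keeps
   the low set at or below its 25th p-value percentile, high keeps the
   medium set at or below its 50th percentile. The union set is the
   duplicate-free concatenation.
3. **Cluster** (`compute_pca()`, `build_snn()`, `leiden_tuned()`):
   PCA (up to 50 components) on the selected genes, a shared-nearest-
   neighbour graph (k = 15, Jaccard edge weights), and Leiden
   community detection tuned so the number of clusters matches the
   ground truth. K-means with euclidean, Pearson or Spearman distance
   is available as an alternative.
4. **Match and evaluate** (`match_labels()`, `evaluate_all()`):
   predicted clusters are mapped onto the truth vocabulary by
   correlating mean expression profiles, then scored with AMI,
   weighted F1, Pearson Gamma, Spatial Concordance and Mean Spatial
   AMI.
5. **Test and rank** (`significance_matrix()`,
   `summarize_rankings()`): per metric, gene-set pairs are compared
   with paired sign-flip permutation tests (10,000 permutations by
   default) and summarized as mean-value rankings.

## The spatially adjusted metrics

Both spatial metrics weight each cell by the Shannon entropy of the
ground-truth labels in its local spatial neighbourhood (the cell plus
its `k_spatial` nearest tissue neighbours): cells deep inside a
homogeneous domain carry weight close to zero, cells on a domain
border carry the most weight. With normalized weights
`w_i = e_i / sum(e)`:

* **Spatial Concordance**: `SC = sum_i w_i * 1[u_i == u*_i]` — an
  entropy-weighted accuracy that prioritizes edge cases on domain
  borders. It is invariant to the entropy log base, and reduces to
  plain accuracy on a spatially pure tissue (uniform fallback weights
  when all entropies vanish).
* **Mean Spatial AMI**: the adjusted mutual information between truth
  and prediction restricted to each neighbourhood, averaged with the
  same weights and clipped to `[0, 1]`.

Neighbourhoods this small constantly hit AMI's degenerate cases, so
the conventions are explicit: identical restricted partitions
(including the single-label case) score 1; a vanishing normalizer on
non-identical partitions scores 0. AMI itself uses the hypergeometric
expected-MI correction with arithmetic-mean normalization, the
dominant modern convention.

## The synthetic tissue generator

Real benchmark collections cannot ship with a package, so the
generator builds tissues in which HV and SV selections are
complementary *by construction*:

* Cells are placed in the unit square and partitioned into spatial
  domains (vertical stripes, Voronoi cells of random seed points, or a
  jittered lattice). Each domain hosts one **localized** cell type.
* A configurable fraction of cells (default 0.3) is reassigned,
  uniformly over the tissue, to **dispersed** cell types that have no
  spatial preference.
* **SV genes** modulate a flat base mean by a spatial pattern
  (Gaussian hotspot, linear gradient, or sinusoid), independent of
  cell type. **HV marker genes** multiply the base mean by
  `exp(lfc)` in one assigned cell type, independent of position given
  the type; dispersed types are assigned markers first so they are
  always covered. **Noise genes** keep the flat base mean.
* Counts are negative binomial with variance `mu + mu^2/theta`,
  scaled by per-cell lognormal library-size factors applied to the
  means (keeping the NB family closed). Mean surfaces are stored
  alongside the counts so tests can assert the construction directly.

Because SV genes ignore dispersed-type identity and dispersed-type
markers ignore position, SV-only clustering cannot separate the
dispersed types while HV-only clustering can — the regime in which the
union gene set helps.

Defaults (chosen once as a realistic scaled-down tissue and then
frozen): 600 cells, 4 stripe domains with one localized type each, 2
dispersed types at fraction 0.3, 60 SV + 80 HV + 80 noise genes, base
mean 5 counts, marker log fold change 1.5, spatial amplitude 0.8,
`theta = 100` (matching the Pearson-residual null, so noise genes
calibrate to residual variance near 1), library-size sigma 0.2. Under
these conditions the median HV/SV selection overlap
`|hv ∩ sv| / |union|` is about 0.43 — overlapping but clearly
distinct sets, as observed in real tissues.

What the generator does **not** emulate: segmentation errors,
doublets, platform-specific probe panels, batch effects, and the
cell-type granularity of real atlases. Passing benchmarks on these
tissues demonstrates correctness of the machinery and the qualitative
complementarity effect, not performance on any particular platform.

## Numerical and design choices

* **Outlier rule.** "Statistical outliers" is concretized as Tukey
  fences (1.5 IQR) on mean expression — robust, parameter-light and
  testable. A zero-IQR distribution is treated as having no outliers
  (otherwise every non-modal value would be removed from a constant
  matrix). Genes are filtered before cells.
* **SV medium/high nesting.** Literal percentile cutoffs (25th for
  medium, 50th for high) would make the high set *larger* than the
  medium set; the levels are therefore implemented as sequential
  quantile nesting inside the low set, which preserves the intended
  monotone shrinkage. HV percentiles are taken over candidate genes
  only, keeping the candidacy rule meaningful.
* **Leiden tuning.** The resolution grid is 0.1–2.0 in steps of 0.1,
  10 runs per resolution with seeds 0–9, modularity objective. The
  resolution with the most runs hitting the target cluster count wins
  (ties: smallest resolution); among its hits the medoid partition by
  mean pairwise adjusted Rand is returned — deterministic and
  representative. If the target count never appears the grid expands
  geometrically (upper bound doubled, smallest value halved) up to
  three times before erroring.
* **Correlation-distance k-means** is realized by per-cell row
  standardization (after a rank transform for Spearman) followed by
  euclidean k-means — equivalent up to scale to optimizing the
  correlation objective, and it keeps a single well-tested optimizer.
* **Profile matching.** All gene sets of one experiment are matched in
  the union-level gene space, so weighted F1 is comparable across gene
  sets. Equal cluster/class counts use optimal one-to-one assignment
  (Hungarian method) on the profile correlation matrix; unequal counts
  fall back to best-correlated many-to-one matching; a zero-variance
  profile falls back to euclidean distance with a warning.
* **Spatial neighbourhood size** defaults to `k_spatial = 15`,
  mirroring the sNN k; the neighbourhood includes the focal cell so
  single-cell tissues degenerate gracefully. Distance ties break by
  cell index for determinism.
* **Pearson Gamma** is computed over all point pairs up to 2000 cells
  and on a seeded uniform subsample of 2000 beyond that.
* **Permutation tests** are two-sided on the mean paired difference.
  With 12 or fewer pairs the 2^n sign patterns are enumerated exactly
  (no add-one correction); Monte-Carlo p-values carry the add-one
  correction and therefore never report zero.
* **Problem sizes.** The shipped study conditions are 10 tissues of
  600 cells and 220 genes (dataset seeds 0–9), with 499 Moran
  permutations per gene inside the benchmark and 10,000 permutations
  for the paired tests; at these sizes a full run completes in a few
  minutes on one core while leaving all qualitative contrasts intact.

## A worked miniature

```{r mini, eval = FALSE}
library(svhvbench)

config <- list(
  datasets = lapply(0:9, function(s)
    generate_dataset(synthetic_config(seed = s))),
  moran_n_perm = 499, seed = 0)
records <- run_benchmark(config)

aggregate(value ~ metric + gene_set, records, median)
significance_matrix(records[records$metric == "ami", ],
                    pairs = list(c("union", "sv"), c("union", "hv")))
summarize_rankings(records[records$gene_set != "all", ])
```

On the shipped study conditions the union set's median AMI (1.00)
matches HV alone (1.00) and clearly exceeds SV alone (about 0.88),
with the paired union-vs-SV test at the exact enumeration floor
p = 2/1024; the same ordering holds for Spatial Concordance. This
reproduces, at desk scale, the qualitative conclusion that adding HV
genes to SV genes improves cell-type clustering, and that the gain
comes from spatially dispersed cell types invisible to SV selection.

## Known limitations

* The Moran's I permutation scorer is deliberately simple plumbing; it
  is not a replacement for model-based SV detectors, whose p-values
  can be supplied from file instead.
* Ground-truth labels are required for every supervised and spatial
  metric; only Pearson Gamma is unsupervised.
* Metrics are computed per dataset; cross-dataset integration and
  batch correction are out of scope.
* The tuned Leiden step conditions on the true number of clusters, as
  benchmark designs do; it is not an unsupervised model-selection
  procedure.
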