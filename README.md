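# svhvbench

Benchmarking **highly variable (HV)** versus **spatially variable
(SV)** gene sets for cell-type clustering in spatial transcriptomics.

## The problem

Spatial transcriptomics assays measure a cells × genes count matrix
together with each cell's (or spot's) tissue coordinates. Before
clustering, practitioners select informative genes: HV genes (variance
across cells exceeding the expectation at their mean, position
ignored) or SV genes (expression spatially autocorrelated over the
tissue, e.g. detected by SPARK). The two sets are related but
distinct, and clustering on either alone can bias downstream cell-type
annotation. `svhvbench` is a pipeline for measuring — on real data
with ground-truth labels, or on simulated tissues with known structure
— whether the **union** (concatenation) of HV and SV genes clusters
cell types better than either set alone.

## What it computes

For every dataset × gene set (`hv`, `sv`, `union`, `all`) the pipeline
runs: outlier and small-cell-type filtering → normalization (analytic
Pearson residuals, `r = (x − μ)/√(μ + μ²/θ)` with `θ = 100`, or
rescale + log-normalization) → gene selection at low/medium/high
stringency → PCA → shared-nearest-neighbour graph → resolution-tuned
multi-seed Leiden (or k-means with euclidean/Pearson/Spearman
distance) → expression-profile matching of clusters onto the truth
vocabulary → five metrics:

| metric | kind | definition |
|---|---|---|
| AMI | supervised | adjusted mutual information, hypergeometric correction |
| weighted F1 | supervised | class-size-weighted F1 after profile matching |
| Pearson Gamma | unsupervised | cor(pairwise distance, different-cluster indicator) |
| Spatial Concordance | spatial | entropy-weighted accuracy, `SC = Σᵢ wᵢ·1[uᵢ = u*ᵢ]` |
| Mean Spatial AMI | spatial | entropy-weighted mean of per-neighbourhood AMI |

The spatial metrics weight each cell by the Shannon entropy `eᵢ` of
ground-truth labels in its local spatial neighbourhood
(`wᵢ = eᵢ/Σⱼeⱼ`), so agreement on spatial-domain borders counts more
than agreement deep inside homogeneous regions. Gene-set pairs are
compared with paired sign-flip permutation tests (exact enumeration up
to 12 datasets, Monte-Carlo with 10,000 permutations beyond).

A negative-binomial tissue simulator ships with the package: spatial
domains host localized cell types (driving SV genes), dispersed cell
types are distinguishable only through non-spatial markers (driving HV
genes), so HV/SV complementarity holds by construction and every stage
is testable without downloads.

## Worked example

```r
library(svhvbench)

config <- list(
  datasets = lapply(0:9, function(s)
    generate_dataset(synthetic_config(seed = s))),
  moran_n_perm = 499, seed = 0)
records <- run_benchmark(config)

aggregate(value ~ metric + gene_set, records, median)
#>                 metric gene_set     value   (excerpt)
#>                    ami       hv 1.0000000
#>                    ami       sv 0.8843990
#>                    ami    union 1.0000000
#>    spatial_concordance       sv 0.8565029
#>    spatial_concordance    union 1.0000000

significance_matrix(records[records$metric == "ami", ],
                    pairs = list(c("union", "sv")))
#>   metric set_a set_b  mean_diff     p_value stars n_datasets
#> 1    ami union    sv 0.07744577 0.001953125   ***         10
```

Reading: on ten simulated tissues the union gene set matches HV genes
and beats SV genes alone on every metric; the paired permutation test
for union vs SV on AMI is at the exact-enumeration floor (p = 2/1024),
i.e. the union won on all ten tissues. SV-only clustering cannot
separate the spatially dispersed cell types — exactly the gap the
added HV markers close.

File-based datasets are supplied as manifest entries
(`dataset_id`, `counts` (MatrixMarket + sidecars or dense CSV),
`coords`, `labels`, optional `sv_pvalues` from an external SV
detector; without `sv_pvalues` a built-in Moran's I permutation scorer
is used).

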