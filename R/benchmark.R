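# Multi-dataset orchestration, paired sign-flip permutation tests,
# star annotations, and ranking summaries.

#' Paired permutation test on per-dataset metric values
#'
#' Tests the mean paired difference `mean(a - b)` against a null
#' generated by independent sign flips of the differences. Two-sided.
#' For `n <= 12` pairs the 2^n sign patterns are enumerated exactly
#' (no add-one correction); otherwise a Monte-Carlo p-value with the
#' add-one correction `(1 + #\{|mean| >= |obs|\}) / (1 + n_perm)` is
#' returned. All-zero differences give `p = 1`.
#'
#' @param values_a,values_b equal-length numeric vectors paired by
#'   dataset (`n >= 2`).
#' @param n_perm Monte-Carlo permutations (default 10000).
#' @param seed integer seed (Monte-Carlo path only).
#' @return An object of class `paired_perm_test`: list with
#'   `mean_diff`, `p_value`, `n_datasets`, `n_permutations`, `method`
#'   (`"exact"` or `"monte_carlo"`), `seed`.
#' @export
paired_permutation_test <- function(values_a, values_b, n_perm = 10000,
                                    seed = 0L) {
  if (length(values_a) != length(values_b))
    stop("paired vectors differ in length")
  n <- length(values_a)
  if (n < 2) stop("need at least 2 paired observations")
  d <- values_a - values_b
  obs <- mean(d)
  eps <- 1e-12
  if (all(d == 0)) {
    return(structure(list(mean_diff = 0, p_value = 1, n_datasets = n,
                          n_permutations = 0L, method = "degenerate",
                          seed = seed),
                     class = "paired_perm_test"))
  }
  if (n <= 12) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    means <- as.vector(signs %*% d) / n
    p <- mean(abs(means) >= abs(obs) - eps)
    method <- "exact"; n_used <- nrow(signs)
  } else {
    means <- with_seed(seed, {
      flips <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE),
                      nrow = n)
      as.vector(crossprod(flips, d)) / n
    })
    p <- (1 + sum(abs(means) >= abs(obs) - eps)) / (1 + n_perm)
    method <- "monte_carlo"; n_used <- n_perm
  }
  structure(list(mean_diff = obs, p_value = p, n_datasets = n,
                 n_permutations = n_used, method = method, seed = seed),
            class = "paired_perm_test")
}

#' @export
print.paired_perm_test <- function(x, ...) {
  cat(sprintf(
    "paired_perm_test: mean diff %.4g, p = %.4g (%s, n = %d)\n",
    x$mean_diff, x$p_value, x$method, x$n_datasets))
  invisible(x)
}

#' Star annotation for a p-value
#'
#' Bins: `****` p < 1e-3; `***` 1e-3 <= p < 1e-2; `**` 1e-2 <= p <
#' 5e-2; `*` 5e-2 <= p < 0.1; `ns` otherwise.
#'
#' @param p p-value(s) in `[0, 1]`.
#' @return Character vector of star annotations.
#' @export
p_stars <- function(p) {
  vapply(p, function(pp) {
    if (pp < 1e-3) "****"
    else if (pp < 1e-2) "***"
    else if (pp < 5e-2) "**"
    else if (pp < 0.1) "*"
    else "ns"
  }, character(1))
}

# Load one manifest entry into (matrix, coords, truth, sv_pvalues).
load_benchmark_entry <- function(entry) {
  if (inherits(entry, "synthetic_dataset")) {
    return(list(id = paste0("synthetic_seed", entry$config$seed),
                matrix = entry$matrix, coords = entry$coords,
                truth = entry$truth, sv_pvalues = NULL,
                normalization = "pearson"))
  }
  stopifnot(is.list(entry), !is.null(entry$dataset_id))
  counts <- read_counts(entry$counts,
                        format = entry$format %||% "mtx_triplet",
                        orientation = entry$orientation)
  # an unreadable SV p-value table must only cost the sv/union
  # combinations, not the whole dataset
  sv <- if (!is.null(entry$sv_pvalues))
    tryCatch(read_gene_pvalues(entry$sv_pvalues), error = function(e) e)
  else NULL
  list(id = entry$dataset_id, matrix = counts,
       coords = read_coords(entry$coords),
       truth = read_labels(entry$labels),
       sv_pvalues = sv,
       normalization = entry$normalization %||% "pearson")
}

#' Run the full benchmark over a dataset manifest
#'
#' For each dataset x gene set (hv, sv, union, all) x method:
#' preprocess, select genes, cluster, match predicted clusters to the
#' truth vocabulary, and evaluate the five metrics. Failures are
#' isolated per combination: the run continues and the failed
#' combination's records are absent (logged in the `"failures"`
#' attribute; the `"partial"` attribute flags incomplete runs).
#'
#' Datasets may be `synthetic_dataset` objects or lists of file paths
#' (`dataset_id`, `counts`, `coords`, `labels`, optional `sv_pvalues`,
#' optional `normalization`, `format`, `orientation`). When no SV
#' p-value file is supplied the built-in Moran's I permutation scorer
#' is used on the normalized matrix.
#'
#' @param config list with elements:
#'   `datasets` (non-empty manifest list);
#'   `gene_sets` (default `c("hv", "sv", "union", "all")`);
#'   `level` (selection stringency, default `"low"`);
#'   `methods` (default `"leiden"`; also `"kmeans"`);
#'   `kmeans_distance` (default `"euclidean"`);
#'   `n_pcs` (50), `snn_k` (15), `spatial_k` (15),
#'   `moran_k` (6), `moran_n_perm` (999), `seed` (0),
#'   `min_celltype_frac` (0.05), `theta` (100).
#' @return A data frame of metric records (io-module schema), with
#'   attributes `failures` and `partial`.
#' @export
run_benchmark <- function(config) {
  if (is.null(config$datasets) || length(config$datasets) == 0)
    stop("empty dataset manifest")
  gene_sets <- config$gene_sets %||% c("hv", "sv", "union", "all")
  level <- config$level %||% "low"
  methods <- config$methods %||% "leiden"
  n_pcs <- config$n_pcs %||% 50
  snn_k <- config$snn_k %||% 15
  spatial_k <- config$spatial_k %||% 15
  moran_k <- config$moran_k %||% 6
  moran_n_perm <- config$moran_n_perm %||% 999
  seed <- config$seed %||% 0L
  records <- list()
  failures <- character(0)
  for (entry in config$datasets) {
    ds <- tryCatch(load_benchmark_entry(entry), error = function(e) e)
    if (inherits(ds, "error")) {
      failures <- c(failures, paste0("load: ", conditionMessage(ds)))
      next
    }
    res <- tryCatch({
      prep <- preprocess_pipeline(ds$matrix, ds$truth,
                                  normalization = ds$normalization,
                                  min_celltype_frac =
                                    config$min_celltype_frac %||% 0.05,
                                  theta = config$theta %||% 100)
      coords <- align_to_matrix(prep$matrix, ds$coords)
      hv_tab <- if (ds$normalization == "pearson")
        hv_residual_variance(prep$matrix)
      else hv_loess_cv(prep$raw)
      hv <- threshold_hv(hv_tab, level = level)
      list(prep = prep, coords = coords, hv = hv)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures,
                    paste0(ds$id, "/preprocess: ",
                           conditionMessage(res)))
      next
    }
    prep <- res$prep
    sv <- tryCatch({
      sv_tab <- if (!is.null(ds$sv_pvalues)) {
        if (inherits(ds$sv_pvalues, "error"))
          stop("SV p-value table unavailable: ",
               conditionMessage(ds$sv_pvalues))
        idx <- match(prep$matrix$gene_ids, ds$sv_pvalues$gene_ids)
        if (any(is.na(idx)))
          stop("SV p-values missing for ", sum(is.na(idx)), " genes")
        gene_stat_table(prep$matrix$gene_ids,
                        ds$sv_pvalues$statistic[idx], "p_value")
      } else {
        sv_score_moran(prep$matrix, res$coords, k_neighbors = moran_k,
                       n_perm = moran_n_perm, seed = seed)
      }
      threshold_sv(sv_tab, level = level)
    }, error = function(e) e)
    selections <- list(
      hv = res$hv,
      sv = sv,
      union = if (inherits(sv, "error")) sv
              else concatenate_selections(res$hv, sv),
      all = gene_selection("all", level, prep$matrix$gene_ids))
    res$selections <- selections
    target_k <- nlevels(prep$truth$labels)
    union_sel <- if (inherits(selections$union, "error"))
      selections$all else selections$union
    for (gs in gene_sets) {
      sel <- res$selections[[gs]]
      if (inherits(sel, "error")) {
        failures <- c(failures,
                      paste0(ds$id, "/", gs, ": ",
                             conditionMessage(sel)))
        next
      }
      for (method in methods) {
        rec <- tryCatch({
          if (length(sel$gene_ids) == 0) stop("empty selection")
          emb <- compute_pca(res$prep$matrix, sel, n_pcs = n_pcs)
          clus <- if (method == "leiden") {
            leiden_tuned(build_snn(emb, k_neighbors = snn_k),
                         target_k = target_k)
          } else {
            kmeans_cluster(emb, k = target_k,
                           distance = config$kmeans_distance %||%
                             "euclidean",
                           seed = seed)
          }
          matched <- match_labels(clus, res$prep$truth,
                                  res$prep$matrix,
                                  selection = union_sel)
          evaluate_all(matched, emb, res$coords,
                       config = list(
                         k_spatial = spatial_k,
                         gamma_seed = seed,
                         kmeans_distance = config$kmeans_distance %||%
                           "euclidean"),
                       dataset = ds$id, gene_set = gs,
                       threshold = level, method = method)
        }, error = function(e) e)
        if (inherits(rec, "error")) {
          failures <- c(failures,
                        paste0(ds$id, "/", gs, "/", method, ": ",
                               conditionMessage(rec)))
        } else {
          records[[length(records) + 1]] <- rec
        }
      }
    }
  }
  out <- if (length(records)) do.call(rbind, records)
         else stop("no benchmark combination succeeded; first failure: ",
                   failures[1])
  rownames(out) <- NULL
  attr(out, "failures") <- failures
  attr(out, "partial") <- length(failures) > 0
  out
}

#' Paired permutation tests between gene sets over a record table
#'
#' For each metric and each gene-set pair, pairs the per-dataset metric
#' values strictly by dataset id and runs
#' [paired_permutation_test()]; star categories follow [p_stars()].
#'
#' @param records metric-record data frame (one value per dataset x
#'   gene set x metric after filtering to one method/threshold).
#' @param pairs list of 2-element character vectors of gene-set names,
#'   e.g. `list(c("union", "sv"))`.
#' @param n_perm permutations (default 10000).
#' @param seed integer seed.
#' @return Data frame with columns `metric, set_a, set_b, mean_diff,
#'   p_value, stars, n_datasets`.
#' @export
significance_matrix <- function(records, pairs, n_perm = 10000,
                                seed = 0L) {
  out <- list()
  for (metric in unique(records$metric)) {
    rm_ <- records[records$metric == metric, ]
    for (pair in pairs) {
      a <- rm_[rm_$gene_set == pair[1], c("dataset", "value")]
      b <- rm_[rm_$gene_set == pair[2], c("dataset", "value")]
      common <- intersect(a$dataset, b$dataset)
      if (length(common) < 2)
        stop("fewer than 2 common datasets for pair (", pair[1], ", ",
             pair[2], ") on metric ", metric)
      av <- a$value[match(common, a$dataset)]
      bv <- b$value[match(common, b$dataset)]
      tst <- paired_permutation_test(av, bv, n_perm = n_perm,
                                     seed = seed)
      out[[length(out) + 1]] <- data.frame(
        metric = metric, set_a = pair[1], set_b = pair[2],
        mean_diff = tst$mean_diff, p_value = tst$p_value,
        stars = p_stars(tst$p_value), n_datasets = tst$n_datasets,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Mean-metric ranking of gene sets
#'
#' Per metric: the mean value of each gene set across datasets and its
#' rank (1 = best, higher mean is better for every metric including
#' Pearson Gamma).
#'
#' @param records metric-record data frame.
#' @return Data frame with columns `metric, gene_set, mean_value, rank`,
#'   ordered by metric then rank.
#' @export
summarize_rankings <- function(records) {
  if (nrow(records) == 0) stop("no records")
  agg <- stats::aggregate(value ~ metric + gene_set, data = records,
                          FUN = mean)
  names(agg)[names(agg) == "value"] <- "mean_value"
  parts <- lapply(split(agg, agg$metric), function(df) {
    df$rank <- rank(-df$mean_value, ties.method = "min")
    df[order(df$rank, df$gene_set), ]
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out[, c("metric", "gene_set", "mean_value", "rank")]
}
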