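# PCA -> sNN -> Leiden (resolution-tuned, multi-seed) or kmeans, plus
# expression-profile matching of predicted clusters to truth classes.

#' Principal-component embedding of a gene selection
#'
#' Restricts the matrix to the selection, centres features (optionally
#' unit-scales them on the lognorm layer) and takes the top principal
#' components. The number of PCs is capped at
#' `min(n_pcs, n_genes - 1, n_cells - 1)`. Each component carries a
#' deterministic sign convention: the largest-magnitude loading is
#' positive (first index on ties).
#'
#' @param em an [expression_matrix()] (lognorm or pearson layer).
#' @param selection a non-empty [gene_selection()].
#' @param n_pcs requested number of components (default 50).
#' @param scale_features unit-scale features before PCA (default FALSE;
#'   only meaningful on the lognorm layer).
#' @return An object of class `embedding`: list with `cell_ids`,
#'   `coordinates` (cells x PCs), `n_pcs`, `sdev`, `selection`.
#' @export
compute_pca <- function(em, selection, n_pcs = 50,
                        scale_features = FALSE) {
  stopifnot(inherits(em, "expression_matrix"),
            inherits(selection, "gene_selection"))
  if (length(selection$gene_ids) == 0) stop("empty gene selection")
  x <- dense_values(subset_matrix(em, genes = selection$gene_ids))
  k <- as.integer(min(n_pcs, ncol(x) - 1, nrow(x) - 1))
  if (k < 1) k <- 1L
  pr <- stats::prcomp(x, center = TRUE, scale. = scale_features,
                      rank. = k)
  flip <- vapply(seq_len(ncol(pr$rotation)), function(j) {
    l <- pr$rotation[, j]
    sign(l[which.max(abs(l))]) < 0
  }, logical(1))
  scores <- pr$x
  scores[, flip] <- -scores[, flip]
  structure(list(cell_ids = em$cell_ids,
                 coordinates = unname(scores[, seq_len(k), drop = FALSE]),
                 n_pcs = k, sdev = pr$sdev[seq_len(k)],
                 selection = list(source = selection$source,
                                  level = selection$level,
                                  n_genes = length(selection$gene_ids))),
            class = "embedding")
}

#' @export
print.embedding <- function(x, ...) {
  cat(sprintf("embedding: %d cells x %d PCs (selection %s/%s)\n",
              length(x$cell_ids), x$n_pcs,
              x$selection$source, x$selection$level))
  invisible(x)
}

# k nearest neighbours by euclidean distance in a coordinate matrix.
# Self excluded; ties broken by index. Returns n x k index matrix.
knn_indices <- function(coords, k) {
  n <- nrow(coords)
  d <- as.matrix(stats::dist(coords))
  res <- vapply(seq_len(n), function(i) {
    ord <- order(d[i, ], seq_len(n))
    ord[ord != i][seq_len(k)]
  }, integer(k))
  if (k == 1) matrix(res, ncol = 1) else t(res)
}

#' Shared-nearest-neighbour graph
#'
#' Builds kNN sets by euclidean distance in the embedding (self
#' excluded, distance ties broken by cell index), then connects every
#' pair of cells with the Jaccard overlap of their kNN sets; zero-weight
#' edges are pruned.
#'
#' @param embedding an `embedding` from [compute_pca()] (or any list
#'   with `cell_ids` and `coordinates`).
#' @param k_neighbors kNN set size (default 15).
#' @return An [igraph::graph] with edge attribute `weight` in (0, 1].
#' @export
build_snn <- function(embedding, k_neighbors = 15) {
  n <- length(embedding$cell_ids)
  if (n <= k_neighbors)
    stop("need more cells (", n, ") than k_neighbors (", k_neighbors, ")")
  nn <- knn_indices(embedding$coordinates, k_neighbors)
  a <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k_neighbors),
                            j = as.vector(t(nn)), x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(a)          # |kNN(i) inter kNN(j)|
  jac <- shared
  jac@x <- jac@x / (2 * k_neighbors - jac@x)  # |A inter B| / |A union B|
  Matrix::diag(jac) <- 0
  jac <- Matrix::drop0(jac)
  g <- igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                           weighted = TRUE)
  igraph::V(g)$name <- embedding$cell_ids
  g
}

new_clustering_result <- function(cell_ids, cluster_labels, method,
                                  params) {
  cluster_labels <- factor(cluster_labels)
  structure(list(cell_ids = cell_ids, cluster_labels = cluster_labels,
                 method = method, params = params,
                 n_clusters = nlevels(cluster_labels)),
            class = "clustering_result")
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("clustering_result: %s, %d cells, %d clusters\n",
              x$method, length(x$cell_ids), x$n_clusters))
  invisible(x)
}

#' Resolution-tuned multi-seed Leiden clustering
#'
#' For each resolution in the grid, Leiden (modularity objective) is run
#' `n_runs` times under the given seeds. The resolution whose runs hit
#' exactly `target_k` clusters most often is kept (ties: smallest
#' resolution), and among that resolution's `target_k` runs the medoid
#' partition is returned (highest mean pairwise adjusted Rand agreement
#' with the others). If no resolution ever yields `target_k`, the grid
#' is expanded geometrically (upper bound doubled, smallest value
#' halved) up to 3 times before erroring.
#'
#' @param graph weighted undirected [igraph::graph] (e.g. from
#'   [build_snn()]).
#' @param target_k target number of clusters (>= 2), normally the
#'   number of ground-truth classes.
#' @param resolution_grid resolutions to scan
#'   (default `seq(0.1, 2, 0.1)`).
#' @param n_runs runs per resolution (default 10).
#' @param seeds integer seeds, one per run (default `0:(n_runs-1)`).
#' @return A `clustering_result` with `method = "leiden"`.
#' @export
leiden_tuned <- function(graph, target_k,
                         resolution_grid = seq(0.1, 2, by = 0.1),
                         n_runs = 10, seeds = seq_len(n_runs) - 1L) {
  if (target_k < 2) stop("target_k must be >= 2")
  if (length(seeds) != n_runs) stop("need one seed per run")
  run_leiden <- function(res, seed) {
    with_seed(seed, igraph::cluster_leiden(
      graph, objective_function = "modularity",
      resolution = res, weights = igraph::E(graph)$weight,
      n_iterations = 3))$membership
  }
  grid <- sort(unique(resolution_grid))
  tried <- numeric(0)
  for (expansion in 0:3) {
    new_res <- setdiff(grid, tried)
    hits <- lapply(new_res, function(res) {
      runs <- lapply(seeds, function(s) run_leiden(res, s))
      keep <- vapply(runs, function(m) length(unique(m)) == target_k,
                     logical(1))
      list(res = res, count = sum(keep), runs = runs[keep])
    })
    tried <- c(tried, new_res)
    counts <- vapply(hits, `[[`, numeric(1), "count")
    if (any(counts > 0)) {
      best <- hits[[which.max(counts)]]  # first max = smallest resolution
      runs <- best$runs
      if (length(runs) == 1) {
        membership <- runs[[1]]
      } else {
        agree <- vapply(seq_along(runs), function(i) {
          mean(vapply(seq_along(runs)[-i], function(j)
            adjusted_rand(runs[[i]], runs[[j]]), numeric(1)))
        }, numeric(1))
        membership <- runs[[which.max(agree)]]
      }
      return(new_clustering_result(
        igraph::V(graph)$name, membership, "leiden",
        params = list(resolution = best$res, n_hits = best$count,
                      n_runs = n_runs, seeds = seeds,
                      target_k = target_k,
                      grid = range(tried))))
    }
    # expand: double the upper bound, halve the smallest value
    step <- min(diff(grid))
    grid <- sort(unique(c(min(grid) / 2, grid,
                          seq(max(grid), max(grid) * 2, by = step))))
  }
  stop("no resolution in [", min(tried), ", ", max(tried),
       "] yielded ", target_k, " clusters")
}

# Row transforms realizing correlation distances for kmeans: pearson =
# per-row standardization, spearman = per-row rank transform then
# standardization; euclidean kmeans on the transformed rows optimizes
# the corresponding correlation objective up to scale.
kmeans_row_transform <- function(x, distance) {
  if (distance == "euclidean") return(x)
  if (distance == "spearman")
    x <- t(apply(x, 1, rank, ties.method = "average"))
  mu <- rowMeans(x)
  s <- apply(x, 1, stats::sd)
  s[s == 0] <- 1
  (x - mu) / s
}

#' Kmeans clustering of an embedding
#'
#' Euclidean distance uses standard kmeans on the PC coordinates;
#' pearson / spearman correlation distances are realized by per-cell
#' row standardization (after rank transform for spearman) followed by
#' euclidean kmeans. Best of `n_init` restarts by within-cluster sum of
#' squares; deterministic under `seed`.
#'
#' @param embedding an `embedding` from [compute_pca()].
#' @param k number of clusters (<= number of cells).
#' @param distance `"euclidean"`, `"pearson"` or `"spearman"`.
#' @param seed integer seed.
#' @param n_init number of restarts (default 10).
#' @return A `clustering_result` with `method = "kmeans"`.
#' @export
kmeans_cluster <- function(embedding, k,
                           distance = c("euclidean", "pearson",
                                        "spearman"),
                           seed = 0L, n_init = 10) {
  distance <- match.arg(distance)
  x <- embedding$coordinates
  n <- nrow(x)
  if (k > n) stop("k (", k, ") exceeds number of cells (", n, ")")
  x <- kmeans_row_transform(x, distance)
  membership <- if (k == n) seq_len(n) else with_seed(seed, {
    stats::kmeans(x, centers = k, nstart = n_init,
                  iter.max = 100)$cluster
  })
  new_clustering_result(embedding$cell_ids, membership, "kmeans",
                        params = list(k = k, distance = distance,
                                      seed = seed, n_init = n_init,
                                      transformed = distance != "euclidean"))
}

#' Match predicted clusters to truth classes by expression profiles
#'
#' Computes the mean expression profile of each predicted cluster and
#' each truth class over a common gene space (conventionally the
#' union-level selection of the experiment) and correlates them. When
#' the cluster count equals the class count, clusters are assigned
#' one-to-one by maximum-total-correlation optimal assignment;
#' otherwise each cluster maps to its best-correlated class
#' (many-to-one). A predicted cluster with a zero-variance profile is
#' assigned to the class with the smallest euclidean profile distance,
#' with a warning.
#'
#' @param clustering a `clustering_result`.
#' @param truth a [label_set()] over the same cells.
#' @param em the [expression_matrix()] used for profiles.
#' @param selection [gene_selection()] defining the profile gene space.
#' @return An object of class `matched_labels`: list with `u` (truth
#'   factor), `u_star` (predictions mapped into the truth vocabulary)
#'   and `mapping` (cluster -> class data frame).
#' @export
match_labels <- function(clustering, truth, em, selection) {
  stopifnot(inherits(clustering, "clustering_result"),
            inherits(truth, "label_set"))
  truth <- align_to_matrix(em, truth)
  idx <- match(em$cell_ids, clustering$cell_ids)
  if (any(is.na(idx))) stop("clustering does not cover the matrix cells")
  pred <- clustering$cluster_labels[idx]
  x <- dense_values(subset_matrix(em, genes = selection$gene_ids))
  profile <- function(f) {
    t(vapply(levels(f), function(l)
      colMeans(x[f == l, , drop = FALSE]), numeric(ncol(x))))
  }
  pp <- profile(pred)                 # clusters x genes
  tp <- profile(truth$labels)         # classes  x genes
  cmat <- matrix(NA_real_, nrow(pp), nrow(tp),
                 dimnames = list(rownames(pp), rownames(tp)))
  for (i in seq_len(nrow(pp))) {
    if (stats::sd(pp[i, ]) == 0) next
    for (j in seq_len(nrow(tp))) {
      if (stats::sd(tp[j, ]) == 0) next
      cmat[i, j] <- stats::cor(pp[i, ], tp[j, ])
    }
  }
  bad <- apply(cmat, 1, function(r) all(is.na(r)))
  if (any(bad)) {
    warning("zero-variance profile for cluster(s) ",
            paste(rownames(pp)[bad], collapse = ", "),
            "; assigning by euclidean profile distance")
    for (i in which(bad)) {
      d <- sqrt(colSums((t(tp) - pp[i, ])^2))
      # negative scaled distance keeps 'larger is better' semantics
      cmat[i, ] <- -d / (max(d) + 1)
    }
  }
  cmat[is.na(cmat)] <- -2  # class-side degenerate: below any correlation
  map_to <- if (nrow(pp) == nrow(tp)) {
    solve_assignment_max(cmat)
  } else {
    max.col(cmat, ties.method = "first")
  }
  mapping <- data.frame(cluster = rownames(pp),
                        class = rownames(tp)[map_to],
                        stringsAsFactors = FALSE)
  u_star <- factor(mapping$class[match(as.character(pred),
                                       mapping$cluster)],
                   levels = levels(truth$labels))
  structure(list(u = truth$labels, u_star = u_star,
                 cell_ids = em$cell_ids, mapping = mapping),
            class = "matched_labels")
}

#' @export
print.matched_labels <- function(x, ...) {
  cat(sprintf("matched_labels: %d cells, %d classes, accuracy %.3f\n",
              length(x$u), nlevels(x$u), mean(x$u == x$u_star)))
  invisible(x)
}
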