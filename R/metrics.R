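# Evaluation metrics: AMI (see ami.R), weighted F1, Pearson Gamma, and
# the two spatially adjusted metrics built on local-entropy weights
# (Spatial Concordance and Mean Spatial AMI).

#' Weighted F1 of matched labels
#'
#' Per truth class, precision and recall of the matched predictions are
#' combined into an F1 score (0 when undefined); the weighted mean uses
#' truth-class frequencies as weights.
#'
#' @param matched a `matched_labels` object (or any list with factors
#'   `u` and `u_star` on one vocabulary).
#' @return A scalar in `[0, 1]`; 1 iff `u_star = u`.
#' @export
weighted_f1 <- function(matched) {
  u <- matched$u; us <- matched$u_star
  if (length(u) != length(us)) stop("label vectors differ in length")
  f1s <- vapply(levels(u), function(cl) {
    tp <- sum(u == cl & us == cl)
    fp <- sum(u != cl & us == cl)
    fn <- sum(u == cl & us != cl)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  w <- as.numeric(table(u)[levels(u)]) / length(u)
  sum(w * f1s)
}

#' Pearson Gamma clustering index
#'
#' Correlation, over all unordered point pairs, between the pairwise
#' distance and the binary membership indicator (0 = same cluster,
#' 1 = different clusters). Higher values mean tighter, better-separated
#' clusters. Beyond `subsample_cap` points a seeded uniform subsample is
#' used.
#'
#' @param labels cluster labels (>= 2 distinct values for a defined
#'   result; a single cluster returns `NaN` with a warning).
#' @param x either a numeric coordinate matrix (euclidean distances) or
#'   a `dist` object.
#' @param subsample_cap maximum number of points used (default 2000).
#' @param seed seed for the subsample.
#' @return A scalar in `[-1, 1]`, or `NaN` for a single cluster.
#' @export
pearson_gamma <- function(labels, x, subsample_cap = 2000, seed = 0L) {
  labels <- as.factor(labels)
  n <- length(labels)
  if (inherits(x, "dist")) {
    if (attr(x, "Size") != n) stop("dist size does not match labels")
    d <- x
  } else {
    x <- as.matrix(x)
    if (nrow(x) != n) stop("coordinate rows do not match labels")
    d <- NULL
  }
  if (n > subsample_cap) {
    keep <- with_seed(seed, sort(sample.int(n, subsample_cap)))
    labels <- labels[keep]
    if (is.null(d)) x <- x[keep, , drop = FALSE]
    else d <- stats::as.dist(as.matrix(d)[keep, keep])
    n <- subsample_cap
  }
  if (length(unique(labels)) < 2) {
    warning("pearson_gamma undefined for a single cluster")
    return(NaN)
  }
  if (is.null(d)) d <- stats::dist(x)
  same <- stats::dist(as.numeric(labels)) > 0  # TRUE = different cluster
  stats::cor(as.numeric(d), as.numeric(same))
}

#' Local spatial neighbourhoods
#'
#' Per-cell euclidean k-nearest-neighbour sets over the tissue
#' coordinates, self included, distance ties broken by cell index.
#'
#' @param coords a [spatial_coords()].
#' @param k_spatial number of neighbours beyond the cell itself
#'   (default 15); each neighbourhood has `k_spatial + 1` members.
#' @return An object of class `spatial_neighborhood`: list with
#'   `members` (list of integer index vectors, self first),
#'   `k_spatial`, `cell_ids`.
#' @export
build_neighborhoods <- function(coords, k_spatial = 15) {
  stopifnot(inherits(coords, "spatial_coords"))
  n <- length(coords$cell_ids)
  if (n <= k_spatial)
    stop("need more cells (", n, ") than k_spatial (", k_spatial, ")")
  nn <- knn_indices(cbind(coords$x, coords$y), k_spatial)
  members <- lapply(seq_len(n), function(i) c(i, nn[i, ]))
  structure(list(members = members, k_spatial = k_spatial,
                 cell_ids = coords$cell_ids),
            class = "spatial_neighborhood")
}

#' @export
print.spatial_neighborhood <- function(x, ...) {
  cat(sprintf("spatial_neighborhood: %d cells, k_spatial=%d\n",
              length(x$members), x$k_spatial))
  invisible(x)
}

#' Local-entropy weights over spatial neighbourhoods
#'
#' For each cell, the Shannon entropy (natural log) of the ground-truth
#' label frequencies within its neighbourhood, normalized to sum 1
#' across cells. A spatially pure tissue (all entropies zero) falls
#' back to uniform weights `1/n`, so Spatial Concordance reduces to
#' plain accuracy there.
#'
#' @param truth truth labels (vector or [label_set()]).
#' @param nb a `spatial_neighborhood` from [build_neighborhoods()].
#' @return An object of class `entropy_weights`: list with `e` (raw
#'   entropies) and `w` (normalized weights summing to 1).
#' @export
entropy_weights <- function(truth, nb) {
  labels <- if (inherits(truth, "label_set")) truth$labels else truth
  labels <- as.factor(labels)
  if (length(labels) != length(nb$members))
    stop("labels do not match neighbourhoods")
  code <- as.integer(labels)
  e <- vapply(nb$members, function(m) {
    entropy_nat(tabulate(code[m], nbins = nlevels(labels)))
  }, numeric(1))
  total <- sum(e)
  w <- if (total == 0) rep(1 / length(e), length(e)) else e / total
  structure(list(e = e, w = w), class = "entropy_weights")
}

#' Spatial Concordance
#'
#' Entropy-weighted label-match rate: `sum_i 1[u_i == u*_i] * w_i` with
#' the normalized local-entropy weights of [entropy_weights()]. A match
#' in a heterogeneous neighbourhood (domain border) counts more than
#' one in a homogeneous region. Invariant to the entropy log base.
#'
#' @param matched a `matched_labels` object.
#' @param weights an `entropy_weights` object.
#' @return A scalar in `[0, 1]`; 1 iff predictions match truth at every
#'   positive-weight cell.
#' @export
spatial_concordance <- function(matched, weights) {
  u <- matched$u; us <- matched$u_star
  if (length(u) != length(weights$w))
    stop("weights do not match labels")
  sum(weights$w[as.character(u) == as.character(us)])
}

# AMI restricted to a neighbourhood, with small-sample conventions:
# identical restricted partitions (including single-label) give 1;
# otherwise standard AMI, with 0 when its normalizer vanishes.
local_ami <- function(u, us, members) {
  uu <- u[members]; vv <- us[members]
  if (same_partition(uu, vv)) return(1)
  ami(uu, vv)
}

#' Mean Spatial AMI
#'
#' The AMI between truth and matched predictions restricted to each
#' cell's spatial neighbourhood, averaged with the same normalized
#' entropy weights as [spatial_concordance()] and clipped to `[0, 1]`
#' (restricted AMI can be slightly negative). Identical restricted
#' partitions score 1, including the single-label case.
#'
#' @param matched a `matched_labels` object.
#' @param nb a `spatial_neighborhood`.
#' @param weights an `entropy_weights` object.
#' @return A scalar in `[0, 1]`; 1 iff `u_star = u`.
#' @export
mean_spatial_ami <- function(matched, nb, weights) {
  u <- as.character(matched$u); us <- as.character(matched$u_star)
  if (length(u) != length(nb$members))
    stop("neighbourhoods do not match labels")
  a <- vapply(seq_along(nb$members), function(i) {
    if (weights$w[i] == 0) return(0)  # zero weight: value irrelevant
    local_ami(u, us, nb$members[[i]])
  }, numeric(1))
  min(max(sum(weights$w * a), 0), 1)
}

#' Evaluate all five metrics for one clustering
#'
#' Emits one metric record per metric: `ami`, `weighted_f1`,
#' `pearson_gamma`, `spatial_concordance`, `mean_spatial_ami`.
#' Pearson Gamma uses euclidean distance on the embedding for
#' Leiden-derived clusterings and the method-appropriate
#' (possibly row-transformed) space for kmeans.
#'
#' @param matched a `matched_labels` object.
#' @param embedding the `embedding` the clustering ran on.
#' @param coords a [spatial_coords()] aligned with the matched cells.
#' @param config list of options: `k_spatial` (default 15),
#'   `gamma_subsample` (default 2000), `gamma_seed` (default 0),
#'   `kmeans_distance` (row transform applied for kmeans-derived
#'   clusterings, default `"euclidean"`).
#' @param dataset,gene_set,threshold,method identifiers copied into the
#'   records.
#' @return A data frame of 5 metric records with columns
#'   `dataset, gene_set, threshold, method, metric, value`.
#' @export
evaluate_all <- function(matched, embedding, coords, config = list(),
                         dataset = "dataset", gene_set = "all",
                         threshold = "low", method = "leiden") {
  k_spatial <- config$k_spatial %||% 15
  gsub_cap <- config$gamma_subsample %||% 2000
  gseed <- config$gamma_seed %||% 0L
  kdist <- config$kmeans_distance %||% "euclidean"
  coords <- if (identical(coords$cell_ids, matched$cell_ids)) coords
            else spatial_coords(matched$cell_ids,
                                coords$x[match(matched$cell_ids,
                                               coords$cell_ids)],
                                coords$y[match(matched$cell_ids,
                                               coords$cell_ids)])
  nb <- build_neighborhoods(coords, k_spatial = k_spatial)
  w <- entropy_weights(matched$u, nb)
  gx <- if (method == "kmeans")
    kmeans_row_transform(embedding$coordinates, kdist)
  else embedding$coordinates
  vals <- c(
    ami = ami(matched$u, matched$u_star),
    weighted_f1 = weighted_f1(matched),
    pearson_gamma = pearson_gamma(matched$u_star, gx,
                                  subsample_cap = gsub_cap, seed = gseed),
    spatial_concordance = spatial_concordance(matched, w),
    mean_spatial_ami = mean_spatial_ami(matched, nb, w))
  data.frame(dataset = dataset, gene_set = gene_set,
             threshold = threshold, method = method,
             metric = names(vals), value = unname(vals),
             stringsAsFactors = FALSE, row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
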