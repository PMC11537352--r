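# Filtering, rescaling and normalization ahead of feature selection.
# Two normalization paths exist: rescale + log-normalization (imaging
# platforms such as merFISH) and analytic Pearson residuals (the rest).

new_preprocess_report <- function(n_genes_removed = 0L, n_cells_removed = 0L,
                                  removed_celltypes = character(),
                                  parameters = list()) {
  structure(list(n_genes_removed = as.integer(n_genes_removed),
                 n_cells_removed = as.integer(n_cells_removed),
                 removed_celltypes = removed_celltypes,
                 parameters = parameters),
            class = "preprocess_report")
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat(sprintf("preprocess_report: %d genes removed, %d cells removed",
              x$n_genes_removed, x$n_cells_removed))
  if (length(x$removed_celltypes))
    cat(" (cell types: ", paste(x$removed_celltypes, collapse = ", "), ")",
        sep = "")
  cat("\n")
  invisible(x)
}

# Tukey-fence outlier flags on a vector of means. A zero IQR makes the
# fences degenerate, so it is treated as "no outliers".
tukey_outliers <- function(m, k = 1.5) {
  q <- stats::quantile(m, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  if (iqr == 0) return(rep(FALSE, length(m)))
  m < q[1] - k * iqr | m > q[2] + k * iqr
}

#' Remove outlier genes and cells by mean expression
#'
#' Per-gene and per-cell mean expression is computed; entries whose mean
#' falls outside the Tukey fences (Q1 - 1.5 IQR, Q3 + 1.5 IQR) of the
#' respective mean distribution are removed. Genes are filtered first,
#' then cell means are recomputed on the retained genes. Retained rows
#' and columns keep their input order.
#'
#' @param em raw-layer [expression_matrix()].
#' @return List with `matrix` (filtered) and `report`
#'   (a `preprocess_report`).
#' @export
filter_outliers <- function(em) {
  stopifnot(inherits(em, "expression_matrix"))
  if (em$layer != "raw") stop("filter_outliers expects raw counts")
  gene_means <- Matrix::colMeans(em$values)
  bad_genes <- tukey_outliers(gene_means)
  if (all(bad_genes)) stop("outlier filter removed all genes")
  out <- subset_matrix(em, genes = which(!bad_genes))
  cell_means <- Matrix::rowMeans(out$values)
  bad_cells <- tukey_outliers(cell_means)
  if (all(bad_cells)) stop("outlier filter removed all cells")
  out <- subset_matrix(out, cells = which(!bad_cells))
  list(matrix = out,
       report = new_preprocess_report(
         n_genes_removed = sum(bad_genes),
         n_cells_removed = sum(bad_cells),
         parameters = list(rule = "tukey", k = 1.5)))
}

#' Remove small-population cell types
#'
#' Cells whose ground-truth class holds strictly less than
#' `min_fraction` of all cells are removed. Frequencies are evaluated
#' once on the input, not iteratively; a class at exactly the threshold
#' is retained.
#'
#' @param em an [expression_matrix()].
#' @param truth a [label_set()] covering the matrix cells.
#' @param min_fraction minimum class frequency (default 0.05).
#' @return List with `matrix`, `truth` (both filtered) and `report`.
#' @export
filter_small_celltypes <- function(em, truth, min_fraction = 0.05) {
  stopifnot(inherits(em, "expression_matrix"), inherits(truth, "label_set"))
  truth <- align_to_matrix(em, truth)
  freq <- table(truth$labels) / length(truth$labels)
  small <- names(freq)[freq < min_fraction]
  keep <- !(as.character(truth$labels) %in% small)
  if (!any(keep)) stop("cell-type filter removed all cells")
  out <- subset_matrix(em, cells = which(keep))
  new_truth <- label_set(truth$cell_ids[keep],
                         as.character(truth$labels)[keep])
  list(matrix = out, truth = new_truth,
       report = new_preprocess_report(
         n_cells_removed = sum(!keep),
         removed_celltypes = small,
         parameters = list(min_fraction = min_fraction)))
}

#' Rescale raw counts by a constant factor
#'
#' Used on imaging-platform data ahead of log-normalization; the layer
#' stays raw-like.
#'
#' @param em raw-layer [expression_matrix()].
#' @param factor positive multiplier (default 1000).
#' @return The rescaled [expression_matrix()].
#' @export
rescale_counts <- function(em, factor = 1000) {
  stopifnot(inherits(em, "expression_matrix"))
  if (em$layer != "raw") stop("rescale_counts expects the raw layer")
  if (!is.numeric(factor) || factor <= 0) stop("factor must be > 0")
  expression_matrix(em$values * factor, em$cell_ids, em$gene_ids,
                    layer = "raw")
}

#' Log-normalize expression
#'
#' Per-cell totals are scaled to the median total across cells, then
#' `log1p` is applied.
#'
#' @param em non-negative [expression_matrix()].
#' @return An [expression_matrix()] with `layer = "lognorm"`.
#' @export
lognormalize <- function(em) {
  stopifnot(inherits(em, "expression_matrix"))
  totals <- Matrix::rowSums(em$values)
  if (any(totals == 0))
    stop("cell(s) with zero total count: ",
         paste(utils::head(em$cell_ids[totals == 0], 5), collapse = ", "))
  target <- stats::median(totals)
  scaled <- Matrix::Diagonal(x = target / totals) %*%
    Matrix::Matrix(em$values, sparse = TRUE)
  out <- log1p(methods::as(scaled, "CsparseMatrix"))
  expression_matrix(out, em$cell_ids, em$gene_ids, layer = "lognorm")
}

#' Analytic Pearson residuals
#'
#' Residuals under an offset negative-binomial null with fixed
#' dispersion: `mu_ij = (row_i total * col_j total) / grand total`,
#' `r_ij = (x_ij - mu_ij) / sqrt(mu_ij + mu_ij^2 / theta)`, clipped to
#' `+/- sqrt(n_cells)`. Entries with `mu_ij = 0` (empty row or column)
#' get residual 0.
#'
#' @param em raw-layer [expression_matrix()].
#' @param theta negative-binomial dispersion of the null (default 100;
#'   `Inf` gives the Poisson limit).
#' @return An [expression_matrix()] with `layer = "pearson"`.
#' @export
pearson_residuals <- function(em, theta = 100) {
  stopifnot(inherits(em, "expression_matrix"))
  if (em$layer != "raw") stop("pearson_residuals expects raw counts")
  x <- dense_values(em)
  rt <- rowSums(x); ct <- colSums(x); gt <- sum(x)
  if (gt == 0) stop("zero grand total")
  mu <- outer(rt, ct) / gt
  denom <- sqrt(mu + mu^2 / theta)
  r <- (x - mu) / denom
  r[mu == 0] <- 0
  clip <- sqrt(nrow(x))
  r[r > clip] <- clip
  r[r < -clip] <- -clip
  expression_matrix(r, em$cell_ids, em$gene_ids, layer = "pearson")
}

#' Run the default preprocessing pipeline
#'
#' Outlier filtering, small-cell-type filtering, then one of the two
#' normalization paths: `"pearson"` (analytic Pearson residuals) or
#' `"lognorm"` (rescale by `rescale_factor`, then log-normalization).
#'
#' @param em raw-layer [expression_matrix()].
#' @param truth a [label_set()].
#' @param normalization `"pearson"` or `"lognorm"`.
#' @param rescale_factor multiplier for the lognorm path (default 1000).
#' @param min_celltype_frac minimum cell-type frequency (default 0.05).
#' @param theta Pearson-residual dispersion (default 100).
#' @return List with `matrix` (normalized), `raw` (filtered raw matrix),
#'   `truth` (filtered) and `reports`.
#' @export
preprocess_pipeline <- function(em, truth,
                                normalization = c("pearson", "lognorm"),
                                rescale_factor = 1000,
                                min_celltype_frac = 0.05, theta = 100) {
  normalization <- match.arg(normalization)
  fo <- filter_outliers(em)
  fc <- filter_small_celltypes(fo$matrix, truth,
                               min_fraction = min_celltype_frac)
  norm <- if (normalization == "pearson") {
    pearson_residuals(fc$matrix, theta = theta)
  } else {
    lognormalize(rescale_counts(fc$matrix, factor = rescale_factor))
  }
  list(matrix = norm, raw = fc$matrix, truth = fc$truth,
       reports = list(outliers = fo$report, celltypes = fc$report))
}
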