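# Lightweight S3 containers shared by every stage of the pipeline.
# All matrices are oriented cells x genes internally; alignment between
# containers is always by id (explicit join), never by row order.

#' Construct an expression matrix container
#'
#' @param values cells x genes numeric matrix (base or [Matrix::Matrix]).
#' @param cell_ids character vector of unique cell/spot ids (rows).
#' @param gene_ids character vector of unique gene ids (columns).
#' @param layer one of `"raw"` (counts), `"lognorm"`, `"pearson"`.
#'   Raw layers must be finite and non-negative.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, cell_ids, gene_ids,
                              layer = c("raw", "lognorm", "pearson")) {
  layer <- match.arg(layer)
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (nrow(values) != length(cell_ids) || ncol(values) != length(gene_ids))
    stop("matrix dimensions (", nrow(values), " x ", ncol(values),
         ") do not match id lengths (", length(cell_ids), " cells, ",
         length(gene_ids), " genes)")
  if (anyDuplicated(cell_ids)) stop("duplicate cell ids")
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids")
  vals <- if (inherits(values, "Matrix")) values@x else values
  if (layer == "raw") {
    if (any(!is.finite(vals))) stop("raw layer contains non-finite values")
    if (any(vals < 0)) stop("raw layer contains negative values")
  } else if (any(is.na(vals))) {
    stop("expression values contain NA")
  }
  dimnames(values) <- list(cell_ids, gene_ids)
  structure(list(values = values, cell_ids = cell_ids,
                 gene_ids = gene_ids, layer = layer),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d cells x %d genes, layer=%s\n",
              length(x$cell_ids), length(x$gene_ids), x$layer))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Construct a spatial coordinate table
#'
#' @param cell_ids unique cell/spot ids.
#' @param x,y finite numeric coordinates in arbitrary tissue units.
#' @return An object of class `spatial_coords`.
#' @export
spatial_coords <- function(cell_ids, x, y) {
  cell_ids <- as.character(cell_ids)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(cell_ids) != length(x) || length(x) != length(y))
    stop("cell_ids, x and y must have equal length")
  if (anyDuplicated(cell_ids)) stop("duplicate cell ids in coordinates")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("non-finite spatial coordinate")
  structure(list(cell_ids = cell_ids, x = x, y = y),
            class = "spatial_coords")
}

#' @export
print.spatial_coords <- function(x, ...) {
  cat(sprintf("spatial_coords: %d cells\n", length(x$cell_ids)))
  invisible(x)
}

#' Construct a label set (ground truth or predicted)
#'
#' Class order is first-appearance order on input.
#'
#' @param cell_ids unique cell/spot ids.
#' @param labels vector of class labels, no missing values.
#' @return An object of class `label_set`.
#' @export
label_set <- function(cell_ids, labels) {
  cell_ids <- as.character(cell_ids)
  if (length(cell_ids) != length(labels))
    stop("cell_ids and labels must have equal length")
  if (length(labels) == 0) stop("label set is empty")
  if (anyDuplicated(cell_ids)) stop("duplicate cell ids in labels")
  if (any(is.na(labels)) || any(as.character(labels) == ""))
    stop("missing label")
  labels <- factor(as.character(labels),
                   levels = unique(as.character(labels)))
  structure(list(cell_ids = cell_ids, labels = labels),
            class = "label_set")
}

#' @export
print.label_set <- function(x, ...) {
  cat(sprintf("label_set: %d cells, %d classes\n",
              length(x$cell_ids), nlevels(x$labels)))
  invisible(x)
}

#' Construct a per-gene statistic table
#'
#' @param gene_ids unique gene ids.
#' @param statistic per-gene real statistic (`-Inf` allowed as sentinel).
#' @param statistic_kind one of `"cv_excess"`, `"residual_variance"`,
#'   `"p_value"`, `"morans_i"`. P-values must lie in `[0, 1]`.
#' @return An object of class `gene_stat_table`.
#' @export
gene_stat_table <- function(gene_ids, statistic,
                            statistic_kind = c("cv_excess",
                                               "residual_variance",
                                               "p_value", "morans_i")) {
  statistic_kind <- match.arg(statistic_kind)
  gene_ids <- as.character(gene_ids)
  statistic <- as.numeric(statistic)
  if (length(gene_ids) != length(statistic))
    stop("gene_ids and statistic must have equal length")
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids")
  if (any(is.na(statistic))) stop("missing statistic value")
  if (statistic_kind == "p_value" &&
      (any(statistic < 0) || any(statistic > 1)))
    stop("p-values must lie in [0, 1]")
  structure(list(gene_ids = gene_ids, statistic = statistic,
                 statistic_kind = statistic_kind),
            class = "gene_stat_table")
}

#' @export
print.gene_stat_table <- function(x, ...) {
  cat(sprintf("gene_stat_table: %d genes, kind=%s\n",
              length(x$gene_ids), x$statistic_kind))
  invisible(x)
}

#' Construct a gene selection
#'
#' @param source one of `"hv"`, `"sv"`, `"union"`, `"all"`.
#' @param level stringency level: `"low"`, `"medium"`, `"high"`.
#' @param gene_ids ordered unique gene ids.
#' @param provenance free-form list recording the statistic and cutoff
#'   that produced the selection.
#' @return An object of class `gene_selection`.
#' @export
gene_selection <- function(source = c("hv", "sv", "union", "all"),
                           level = c("low", "medium", "high"),
                           gene_ids, provenance = list()) {
  source <- match.arg(source)
  level <- match.arg(level)
  gene_ids <- as.character(gene_ids)
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids in selection")
  structure(list(source = source, level = level, gene_ids = gene_ids,
                 provenance = provenance),
            class = "gene_selection")
}

#' @export
print.gene_selection <- function(x, ...) {
  cat(sprintf("gene_selection: %s/%s, %d genes\n",
              x$source, x$level, length(x$gene_ids)))
  invisible(x)
}

#' @export
length.gene_selection <- function(x) length(x$gene_ids)

#' Align a companion table to the cell order of an expression matrix
#'
#' Joins a [spatial_coords()] or [label_set()] onto the matrix's cells
#' by id (never by row order). Matrix cells missing from the companion
#' are an error: silent misalignment would corrupt every downstream
#' metric. Companion rows for cells absent from the matrix (e.g.
#' filtered out) are dropped.
#'
#' @param em an [expression_matrix()].
#' @param companion a [spatial_coords()] or [label_set()].
#' @return The companion, subset and reordered to `em$cell_ids`.
#' @export
align_to_matrix <- function(em, companion) {
  ids <- if (inherits(companion, "spatial_coords") ||
             inherits(companion, "label_set")) companion$cell_ids
         else stop("unsupported companion type")
  idx <- match(em$cell_ids, ids)
  if (any(is.na(idx)))
    stop("cells missing from companion table: ",
         paste(utils::head(em$cell_ids[is.na(idx)], 5), collapse = ", "))
  if (inherits(companion, "spatial_coords"))
    spatial_coords(em$cell_ids, companion$x[idx], companion$y[idx])
  else
    label_set(em$cell_ids, as.character(companion$labels)[idx])
}

#' Subset an expression matrix by cells and/or genes
#'
#' @param em an [expression_matrix()].
#' @param cells,genes character ids or integer indices to keep, in the
#'   requested order; `NULL` keeps everything.
#' @return The subset [expression_matrix()].
#' @export
subset_matrix <- function(em, cells = NULL, genes = NULL) {
  v <- em$values
  ci <- em$cell_ids; gi <- em$gene_ids
  if (!is.null(cells)) {
    keep <- if (is.character(cells)) match(cells, ci) else cells
    if (any(is.na(keep))) stop("unknown cell id in subset")
    v <- v[keep, , drop = FALSE]; ci <- ci[keep]
  }
  if (!is.null(genes)) {
    keep <- if (is.character(genes)) match(genes, gi) else genes
    if (any(is.na(keep))) stop("unknown gene id in subset")
    v <- v[, keep, drop = FALSE]; gi <- gi[keep]
  }
  expression_matrix(v, ci, gi, layer = em$layer)
}

# Dense numeric view of the values (row/col names preserved).
dense_values <- function(em) {
  as.matrix(em$values)
}

# Run expr with a temporary RNG state seeded by `seed`, restoring the
# caller's state afterwards, so generators are pure functions of config.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
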