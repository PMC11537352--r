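# Readers/writers for the on-disk formats the pipeline touches.
# MatrixMarket stays 1-based on disk (format standard); internally
# everything is an expression_matrix oriented cells x genes.

#' Read a count matrix
#'
#' Supports MatrixMarket coordinate triplets with gene-id and cell-id
#' sidecar text files, or a dense CSV whose first column holds cell ids
#' and whose header row holds gene ids. On-disk orientation is declared
#' by `orientation` (MatrixMarket count files are conventionally
#' genes x cells, dense CSVs cells x genes); the result is always
#' normalised to cells x genes with `layer = "raw"`.
#'
#' @param path path to the `.mtx` file or dense CSV.
#' @param format `"mtx_triplet"` or `"dense_csv"`.
#' @param orientation `"genes_x_cells"` or `"cells_x_genes"`; default
#'   depends on `format` as described above.
#' @param gene_file,cell_file sidecar paths for `mtx_triplet`; default
#'   `genes.txt` / `cells.txt` next to `path`.
#' @return An [expression_matrix()] with `layer = "raw"`.
#' @export
read_counts <- function(path, format = c("mtx_triplet", "dense_csv"),
                        orientation = NULL,
                        gene_file = NULL, cell_file = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "mtx_triplet") {
    if (is.null(orientation)) orientation <- "genes_x_cells"
    if (is.null(gene_file)) gene_file <- file.path(dirname(path), "genes.txt")
    if (is.null(cell_file)) cell_file <- file.path(dirname(path), "cells.txt")
    for (f in c(gene_file, cell_file))
      if (!file.exists(f)) stop("sidecar file not found: ", f)
    m <- tryCatch(Matrix::readMM(path),
                  error = function(e) stop("invalid MatrixMarket file ",
                                           path, ": ", conditionMessage(e)))
    genes <- readLines(gene_file)
    cells <- readLines(cell_file)
    if (orientation == "genes_x_cells") m <- Matrix::t(m)
    if (nrow(m) != length(cells))
      stop("matrix has ", nrow(m), " cells but cell sidecar lists ",
           length(cells))
    if (ncol(m) != length(genes))
      stop("matrix has ", ncol(m), " genes but gene sidecar lists ",
           length(genes))
    expression_matrix(methods::as(m, "CsparseMatrix"), cells, genes,
                      layer = "raw")
  } else {
    if (is.null(orientation)) orientation <- "cells_x_genes"
    df <- utils::read.csv(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
    ids <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m)) stop("non-numeric entries in dense count CSV")
    if (orientation == "genes_x_cells") {
      expression_matrix(t(m), colnames(m), ids, layer = "raw")
    } else {
      expression_matrix(m, ids, colnames(m), layer = "raw")
    }
  }
}

#' Write a count matrix
#'
#' Inverse of [read_counts()]; MatrixMarket output is written
#' genes x cells (the conventional on-disk orientation) together with
#' `genes.txt` / `cells.txt` sidecars.
#'
#' @param em an [expression_matrix()].
#' @param path output `.mtx` or CSV path.
#' @param format `"mtx_triplet"` or `"dense_csv"`.
#' @return Invisibly, `path`.
#' @export
write_counts <- function(em, path, format = c("mtx_triplet", "dense_csv")) {
  format <- match.arg(format)
  if (format == "mtx_triplet") {
    m <- Matrix::t(methods::as(Matrix::Matrix(em$values, sparse = TRUE),
                               "generalMatrix"))
    Matrix::writeMM(m, path)
    writeLines(em$gene_ids, file.path(dirname(path), "genes.txt"))
    writeLines(em$cell_ids, file.path(dirname(path), "cells.txt"))
  } else {
    df <- data.frame(id = em$cell_ids, as.matrix(em$values),
                     check.names = FALSE)
    colnames(df) <- c("id", em$gene_ids)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a spatial coordinate table
#'
#' CSV with columns `id, x, y`; on-disk row order is preserved.
#'
#' @param path CSV path.
#' @return A [spatial_coords()].
#' @export
read_coords <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("character", "character", "character"))
  if (!all(c("id", "x", "y") %in% names(df)))
    stop("coordinate CSV must have columns id, x, y")
  x <- suppressWarnings(as.numeric(df$x))
  y <- suppressWarnings(as.numeric(df$y))
  if (any(is.na(x)) || any(is.na(y)))
    stop("non-numeric coordinate in ", path)
  spatial_coords(df$id, x, y)
}

#' Write a spatial coordinate table
#' @param coords a [spatial_coords()].
#' @param path CSV path.
#' @return Invisibly, `path`.
#' @export
write_coords <- function(coords, path) {
  utils::write.csv(data.frame(id = coords$cell_ids, x = coords$x,
                              y = coords$y),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a label table
#'
#' CSV with columns `id, label`; class order is first-appearance order.
#'
#' @param path CSV path.
#' @return A [label_set()].
#' @export
read_labels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (nrow(df) == 0) stop("empty label file: ", path)
  if (!all(c("id", "label") %in% names(df)))
    stop("label CSV must have columns id, label")
  label_set(df$id, df$label)
}

#' Write a label table
#' @param labels a [label_set()].
#' @param path CSV path.
#' @return Invisibly, `path`.
#' @export
write_labels <- function(labels, path) {
  utils::write.csv(data.frame(id = labels$cell_ids,
                              label = as.character(labels$labels)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-gene p-value table
#'
#' CSV with columns `gene, p`, as produced by an external SV detector
#' (e.g. SPARK). P-values outside `[0, 1]` are a validation error.
#'
#' @param path CSV path.
#' @return A [gene_stat_table()] with `statistic_kind = "p_value"`.
#' @export
read_gene_pvalues <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "p") %in% names(df)))
    stop("p-value CSV must have columns gene, p")
  gene_stat_table(df$gene, df$p, statistic_kind = "p_value")
}

#' Write a per-gene p-value table
#' @param table a [gene_stat_table()] with `statistic_kind = "p_value"`.
#' @param path CSV path.
#' @return Invisibly, `path`.
#' @export
write_gene_pvalues <- function(table, path) {
  stopifnot(inherits(table, "gene_stat_table"))
  utils::write.csv(data.frame(gene = table$gene_ids, p = table$statistic),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write metric records
#'
#' Long-format CSV with columns
#' `dataset, gene_set, threshold, method, metric, value`, rows sorted by
#' all key columns for deterministic output.
#'
#' @param records data frame of metric records (one row per observation).
#' @param path CSV path.
#' @return Invisibly, `path`.
#' @export
write_metric_records <- function(records, path) {
  cols <- c("dataset", "gene_set", "threshold", "method", "metric", "value")
  if (nrow(records) == 0) stop("no records to write")
  if (!all(cols %in% names(records)))
    stop("records must have columns ", paste(cols, collapse = ", "))
  records <- records[, cols]
  # unname: a column called "method" must not bind to order()'s argument
  ord <- do.call(order, unname(as.list(records[, cols[-length(cols)]])))
  utils::write.csv(records[ord, ], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read metric records written by [write_metric_records()]
#' @param path CSV path.
#' @return A data frame of metric records.
#' @export
read_metric_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}
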