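# HV / SV / union / all gene selections at graded stringency.

#' HV statistic: excess coefficient of variation over a LOESS trend
#'
#' Fits a LOESS regression of the per-gene coefficient of variation
#' (sd/mean) on the log mean expression and scores each gene by
#' observed CV minus fitted CV. Positive scores are HV candidates.
#' Genes with zero mean receive `-Inf` (never candidates).
#'
#' @param em an [expression_matrix()] on the expression scale used for
#'   the imaging-platform path (raw or rescaled counts).
#' @param loess_span LOESS span (default 0.3, degree 2).
#' @return A [gene_stat_table()] with `statistic_kind = "cv_excess"`.
#' @export
hv_loess_cv <- function(em, loess_span = 0.3) {
  stopifnot(inherits(em, "expression_matrix"))
  x <- dense_values(em)
  if (ncol(x) < 10) stop("need at least 10 genes for the LOESS fit")
  m <- colMeans(x)
  s <- apply(x, 2, stats::sd)
  cv <- ifelse(m > 0, s / m, NA_real_)
  pos <- which(m > 0)
  if (length(pos) < 10) stop("fewer than 10 genes with positive mean")
  df <- data.frame(logm = log(m[pos]), cv = cv[pos])
  fit <- tryCatch(
    stats::loess(cv ~ logm, data = df, span = loess_span, degree = 2),
    error = function(e) stop("LOESS fit failed: ", conditionMessage(e)))
  fitted_cv <- stats::predict(fit, newdata = df)
  stat <- rep(-Inf, ncol(x))
  stat[pos] <- df$cv - fitted_cv
  stat[is.na(stat)] <- -Inf  # genes outside the interpolation range
  gene_stat_table(em$gene_ids, stat, statistic_kind = "cv_excess")
}

#' HV statistic: per-gene variance of Pearson residuals
#'
#' On the Pearson-residual layer, the per-gene residual variance;
#' genes with variance above 1 are HV candidates.
#'
#' @param em an [expression_matrix()] with `layer = "pearson"`.
#' @return A [gene_stat_table()] with
#'   `statistic_kind = "residual_variance"`.
#' @export
hv_residual_variance <- function(em) {
  stopifnot(inherits(em, "expression_matrix"))
  if (em$layer != "pearson")
    stop("hv_residual_variance expects the pearson layer")
  x <- dense_values(em)
  n <- nrow(x)
  v <- (colSums(x^2) - n * colMeans(x)^2) / (n - 1)
  gene_stat_table(em$gene_ids, v, statistic_kind = "residual_variance")
}

hv_level_pct <- c(low = 0.5, medium = 0.7, high = 0.9)

#' Threshold an HV statistic table into a gene selection
#'
#' Candidates are genes passing the candidacy rule (statistic > 0 for
#' `cv_excess`, > 1 for `residual_variance`); the selection keeps the
#' candidates whose statistic is at or above the level's percentile of
#' the candidate statistics (linear-interpolation percentile; 50th /
#' 70th / 90th for low / medium / high). Higher levels are always
#' nested inside lower ones.
#'
#' @param table a [gene_stat_table()] of kind `cv_excess` or
#'   `residual_variance`.
#' @param level `"low"`, `"medium"` or `"high"`.
#' @return A [gene_selection()] with `source = "hv"`; empty (with a
#'   warning) when there are no candidates.
#' @export
threshold_hv <- function(table, level = c("low", "medium", "high")) {
  level <- match.arg(level)
  stopifnot(inherits(table, "gene_stat_table"))
  if (!table$statistic_kind %in% c("cv_excess", "residual_variance"))
    stop("threshold_hv needs a cv_excess or residual_variance table")
  floor_val <- if (table$statistic_kind == "cv_excess") 0 else 1
  cand <- table$statistic > floor_val
  if (!any(cand)) {
    warning("no HV candidate genes; selection is empty")
    return(gene_selection("hv", level, character(0),
                          provenance = list(kind = table$statistic_kind,
                                            candidates = 0)))
  }
  cut <- stats::quantile(table$statistic[cand], hv_level_pct[[level]],
                         names = FALSE, type = 7)
  keep <- cand & table$statistic >= cut
  gene_selection("hv", level, table$gene_ids[keep],
                 provenance = list(kind = table$statistic_kind,
                                   candidacy_floor = floor_val,
                                   percentile = hv_level_pct[[level]],
                                   cutoff = cut,
                                   candidates = sum(cand)))
}

#' Threshold an SV p-value table into a gene selection
#'
#' The low level keeps genes with `p < 0.05`; medium keeps the low
#' genes with `p` at or below the 25th percentile of the low set's
#' p-values; high keeps the medium genes with `p` at or below the 50th
#' percentile of the medium set's p-values. The sequential nesting
#' guarantees high is a subset of medium is a subset of low.
#'
#' @param table a [gene_stat_table()] with
#'   `statistic_kind = "p_value"`.
#' @param level `"low"`, `"medium"` or `"high"`.
#' @param alpha low-level p-value cutoff (default 0.05).
#' @return A [gene_selection()] with `source = "sv"` (possibly empty).
#' @export
threshold_sv <- function(table, level = c("low", "medium", "high"),
                         alpha = 0.05) {
  level <- match.arg(level)
  stopifnot(inherits(table, "gene_stat_table"))
  if (table$statistic_kind != "p_value")
    stop("threshold_sv needs a p_value table")
  p <- table$statistic
  keep <- p < alpha
  cuts <- list(alpha = alpha)
  if (level %in% c("medium", "high") && any(keep)) {
    cut_m <- stats::quantile(p[keep], 0.25, names = FALSE, type = 7)
    keep <- keep & p <= cut_m
    cuts$medium_cutoff <- cut_m
  }
  if (level == "high" && any(keep)) {
    cut_h <- stats::quantile(p[keep], 0.5, names = FALSE, type = 7)
    keep <- keep & p <= cut_h
    cuts$high_cutoff <- cut_h
  }
  gene_selection("sv", level, table$gene_ids[keep],
                 provenance = c(list(kind = "p_value"), cuts))
}

#' Moran's I permutation scores for spatially variable genes
#'
#' A stand-in for an external SV detector so the pipeline runs
#' end-to-end: per-gene Moran's I on the symmetrized kNN spatial weight
#' graph with a one-sided permutation p-value
#' `(1 + #\{permuted I >= observed I\}) / (1 + n_perm)`. Constant genes
#' get `p = 1` by convention.
#'
#' @param em an [expression_matrix()] (any layer).
#' @param coords a [spatial_coords()] covering the matrix cells.
#' @param k_neighbors spatial kNN size (default 6).
#' @param n_perm permutations per gene (default 999).
#' @param seed integer seed.
#' @return A [gene_stat_table()] of p-values, with the observed Moran's
#'   I attached as attribute `"morans_i"`.
#' @export
sv_score_moran <- function(em, coords, k_neighbors = 6, n_perm = 999,
                           seed = 0L) {
  stopifnot(inherits(em, "expression_matrix"))
  coords <- align_to_matrix(em, coords)
  n <- length(em$cell_ids)
  nn <- knn_indices(cbind(coords$x, coords$y), k_neighbors)
  a <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k_neighbors),
                            j = as.vector(t(nn)), x = 1, dims = c(n, n))
  w <- methods::as(pmin(a + Matrix::t(a), 1), "CsparseMatrix")
  s0 <- sum(w)
  x <- dense_values(em)
  g <- ncol(x)
  pvals <- numeric(g)
  obs_i <- rep(NA_real_, g)
  with_seed(seed, {
    for (j in seq_len(g)) {
      z <- x[, j] - mean(x[, j])
      denom <- sum(z^2)
      if (denom == 0) { pvals[j] <- 1; next }
      perm_idx <- vapply(seq_len(n_perm), function(k) sample.int(n),
                         integer(n))
      zz <- cbind(z, matrix(z[perm_idx], nrow = n))
      iall <- (n / s0) * colSums(zz * as.matrix(w %*% zz)) / denom
      obs_i[j] <- iall[1]
      pvals[j] <- (1 + sum(iall[-1] >= iall[1])) / (1 + n_perm)
    }
  })
  out <- gene_stat_table(em$gene_ids, pvals, statistic_kind = "p_value")
  attr(out, "morans_i") <- obs_i
  out
}

#' Concatenate HV and SV selections into the union gene set
#'
#' Set union with duplicates removed; order is the HV order followed by
#' SV-only genes in SV order.
#'
#' @param hv,sv [gene_selection()] objects from the same matrix.
#' @return A [gene_selection()] with `source = "union"`.
#' @export
concatenate_selections <- function(hv, sv) {
  stopifnot(inherits(hv, "gene_selection"), inherits(sv, "gene_selection"))
  genes <- c(hv$gene_ids, setdiff(sv$gene_ids, hv$gene_ids))
  gene_selection("union", hv$level, genes,
                 provenance = list(n_hv = length(hv$gene_ids),
                                   n_sv = length(sv$gene_ids),
                                   n_overlap = length(intersect(
                                     hv$gene_ids, sv$gene_ids))))
}
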