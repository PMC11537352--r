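# Tissue simulator with known HV/SV gene structure. Spatially organised
# domains host localised cell types (driving SV genes); spatially
# dispersed cell types are distinguishable only through non-spatial
# marker genes (driving HV genes); the rest is negative-binomial noise.
# Mean surfaces are stored alongside counts for white-box testing.

#' Configuration for the synthetic tissue generator
#'
#' Defaults describe a scaled-down but structurally realistic tissue:
#' a few hundred cells in the unit square partitioned into spatial
#' domains, each hosting one localised cell type; a fraction of cells
#' belongs to dispersed types scattered uniformly over the tissue.
#' SV genes modulate a flat base mean by a spatial pattern (independent
#' of cell type); HV marker genes up-regulate one assigned cell type
#' (independent of position); noise genes keep the flat base mean.
#' Counts are negative binomial with variance `mu + mu^2/nb_dispersion`,
#' scaled by per-cell lognormal library-size factors.
#'
#' @param n_cells number of cells/spots.
#' @param n_domains number of spatial domains.
#' @param layout `"stripes"` (equal-width vertical bands), `"voronoi"`
#'   (nearest of `n_domains` random seed points) or `"grid"` (jittered
#'   lattice placement, voronoi domains).
#' @param n_localized_types number of domain-tied cell types
#'   (at most `n_domains`).
#' @param n_dispersed_types number of spatially dispersed cell types.
#' @param dispersed_fraction fraction of cells reassigned to dispersed
#'   types, uniformly over the tissue; in `[0, 1)`.
#' @param n_sv_genes,n_hv_genes,n_noise_genes gene counts per class.
#' @param sv_patterns subset of `c("hotspot", "gradient", "periodic")`,
#'   cycled over the SV genes.
#' @param marker_log_fold_change log fold change of a marker gene in its
#'   assigned cell type (> 0).
#' @param sv_amplitude multiplicative amplitude of spatial patterns
#'   (> 0); a pattern value f in `[0, 1]` scales the base mean by
#'   `1 + sv_amplitude * f`.
#' @param nb_dispersion negative-binomial dispersion theta (> 0);
#'   variance is `mu + mu^2/theta`, large theta approaches Poisson.
#' @param libsize_sigma sd of log library-size factors (>= 0).
#' @param base_mean flat base mean count per gene (> 0).
#' @param seed integer seed; every generator output is a pure function
#'   of the config including the seed.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_cells = 600, n_domains = 4,
                             layout = c("stripes", "voronoi", "grid"),
                             n_localized_types = 4, n_dispersed_types = 2,
                             dispersed_fraction = 0.3,
                             n_sv_genes = 60,
                             sv_patterns = c("hotspot", "gradient",
                                             "periodic"),
                             n_hv_genes = 80, n_noise_genes = 80,
                             marker_log_fold_change = 1.5,
                             sv_amplitude = 0.8,
                             nb_dispersion = 100, libsize_sigma = 0.2,
                             base_mean = 5, seed = 1L) {
  layout <- match.arg(layout)
  sv_patterns <- match.arg(sv_patterns, several.ok = TRUE)
  cfg <- list(n_cells = as.integer(n_cells),
              n_domains = as.integer(n_domains), layout = layout,
              n_localized_types = as.integer(n_localized_types),
              n_dispersed_types = as.integer(n_dispersed_types),
              dispersed_fraction = dispersed_fraction,
              n_sv_genes = as.integer(n_sv_genes),
              sv_patterns = sv_patterns,
              n_hv_genes = as.integer(n_hv_genes),
              n_noise_genes = as.integer(n_noise_genes),
              marker_log_fold_change = marker_log_fold_change,
              sv_amplitude = sv_amplitude,
              nb_dispersion = nb_dispersion,
              libsize_sigma = libsize_sigma,
              base_mean = base_mean, seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_cells >= 1, n_domains >= 1, n_localized_types >= 1,
              n_dispersed_types >= 1, n_sv_genes >= 1, n_hv_genes >= 1,
              n_noise_genes >= 0, marker_log_fold_change >= 0,
              sv_amplitude >= 0, nb_dispersion > 0, libsize_sigma >= 0,
              base_mean > 0)
    if (n_localized_types > n_domains)
      stop("n_localized_types must not exceed n_domains")
    if (dispersed_fraction < 0 || dispersed_fraction >= 1)
      stop("dispersed_fraction must lie in [0, 1)")
  })
  structure(cfg, class = "synthetic_config")
}

#' Place cells and assign spatial domains
#'
#' Cells are placed uniformly at random in the unit square (`"grid"`
#' layout: jittered lattice). Each cell belongs to exactly one domain:
#' equal-width vertical bands for `"stripes"`, nearest of `n_domains`
#' random seed points otherwise.
#'
#' @param config a [synthetic_config()].
#' @return List with `coords` (a [spatial_coords()]) and `domains`
#'   (integer domain per cell); voronoi seed points attached as
#'   attribute `"seed_points"` on `domains`.
#' @export
generate_tissue <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_cells
  if (config$n_domains > n) stop("more domains than cells")
  with_seed(config$seed, {
    if (config$layout == "grid") {
      side <- ceiling(sqrt(n))
      gx <- (rep(seq_len(side), side)[seq_len(n)] - 0.5) / side
      gy <- (rep(seq_len(side), each = side)[seq_len(n)] - 0.5) / side
      x <- pmin(pmax(gx + stats::runif(n, -0.3, 0.3) / side, 0), 1)
      y <- pmin(pmax(gy + stats::runif(n, -0.3, 0.3) / side, 0), 1)
    } else {
      x <- stats::runif(n); y <- stats::runif(n)
    }
    coords <- spatial_coords(sprintf("cell%04d", seq_len(n)), x, y)
    if (config$layout == "stripes") {
      domains <- pmin(floor(x * config$n_domains) + 1L, config$n_domains)
      seed_points <- NULL
    } else {
      seed_points <- cbind(stats::runif(config$n_domains),
                           stats::runif(config$n_domains))
      d2 <- outer(x, seed_points[, 1], "-")^2 +
            outer(y, seed_points[, 2], "-")^2
      domains <- max.col(-d2, ties.method = "first")
    }
    domains <- as.integer(domains)
    attr(domains, "seed_points") <- seed_points
    list(coords = coords, domains = domains)
  })
}

#' Assign cell types given spatial domains
#'
#' Each localised type is tied to one domain (domains beyond
#' `n_localized_types` recycle the types); a `dispersed_fraction` of
#' cells, sampled uniformly over the whole tissue, is reassigned
#' uniformly among the dispersed types, independent of location.
#'
#' @param domains integer domain per cell (from [generate_tissue()]).
#' @param config a [synthetic_config()].
#' @param cell_ids cell ids to carry into the label set.
#' @return A [label_set()] with levels `L1..` (localised) and `D1..`
#'   (dispersed).
#' @export
assign_cell_types <- function(domains, config,
                              cell_ids = sprintf("cell%04d",
                                                 seq_along(domains))) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- length(domains)
  loc_type <- ((domains - 1L) %% config$n_localized_types) + 1L
  labels <- paste0("L", loc_type)
  with_seed(config$seed + 1L, {
    n_disp <- round(config$dispersed_fraction * n)
    if (n_disp > 0) {
      which_disp <- sample.int(n, n_disp)
      labels[which_disp] <- paste0(
        "D", sample.int(config$n_dispersed_types, n_disp, replace = TRUE))
    }
  })
  # fixed level order so identical tissues give identical factor levels
  lev <- c(paste0("L", seq_len(config$n_localized_types)),
           paste0("D", seq_len(config$n_dispersed_types)))
  ls <- label_set(cell_ids, labels)
  ls$labels <- factor(as.character(ls$labels),
                      levels = intersect(lev, unique(labels)))
  ls
}

# Spatial pattern surfaces, each mapping (x, y) into [0, 1].
pattern_surface <- function(pattern, x, y, params) {
  switch(pattern,
    hotspot = exp(-((x - params$cx)^2 + (y - params$cy)^2) /
                    (2 * params$sigma^2)),
    gradient = {
      proj <- x * cos(params$angle) + y * sin(params$angle)
      rng <- range(proj)
      if (diff(rng) == 0) rep(0.5, length(x))
      else (proj - rng[1]) / diff(rng)
    },
    periodic = (1 + sin(2 * pi * params$freq * x + params$phase)) / 2,
    stop("unknown pattern ", pattern))
}

#' Generate expression counts for a labelled tissue
#'
#' Builds the per-gene mean surface, then draws negative-binomial counts
#' scaled by lognormal library-size factors. SV means are independent of
#' cell type; HV marker means are independent of position given type.
#'
#' @param truth a [label_set()] of cell types.
#' @param coords a [spatial_coords()] aligned with `truth`.
#' @param config a [synthetic_config()].
#' @return List with `matrix` (raw [expression_matrix()]), `gene_class`
#'   (data frame `gene_id, class, subtype`), `mu` (the cells x genes
#'   mean surface before library-size scaling) and `libsize` (per-cell
#'   factors).
#' @export
generate_expression <- function(truth, coords, config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- length(truth$cell_ids)
  if (!identical(truth$cell_ids, coords$cell_ids))
    stop("truth and coords must share one cell order")
  n_genes <- config$n_sv_genes + config$n_hv_genes + config$n_noise_genes
  gene_ids <- sprintf("gene%04d", seq_len(n_genes))
  classes <- c(rep("sv_pattern", config$n_sv_genes),
               rep("hv_marker", config$n_hv_genes),
               rep("noise", config$n_noise_genes))
  subtypes <- character(n_genes)
  mu <- matrix(config$base_mean, nrow = n, ncol = n_genes,
               dimnames = list(truth$cell_ids, gene_ids))
  with_seed(config$seed + 2L, {
    # SV genes: spatial pattern, cycled over the configured pattern kinds
    pat_kinds <- rep(config$sv_patterns,
                     length.out = config$n_sv_genes)
    for (g in seq_len(config$n_sv_genes)) {
      params <- list(cx = stats::runif(1), cy = stats::runif(1),
                     sigma = 0.15, angle = stats::runif(1, 0, 2 * pi),
                     freq = 2, phase = stats::runif(1, 0, 2 * pi))
      f <- pattern_surface(pat_kinds[g], coords$x, coords$y, params)
      mu[, g] <- config$base_mean * (1 + config$sv_amplitude * f)
      subtypes[g] <- pat_kinds[g]
    }
    # HV markers: round-robin over cell types, dispersed types first so
    # they are covered even with few markers
    lev <- levels(truth$labels)
    disp_first <- c(grep("^D", lev, value = TRUE),
                    grep("^D", lev, value = TRUE, invert = TRUE))
    marker_type <- rep(disp_first, length.out = config$n_hv_genes)
    for (g in seq_len(config$n_hv_genes)) {
      j <- config$n_sv_genes + g
      in_type <- as.character(truth$labels) == marker_type[g]
      mu[in_type, j] <- config$base_mean *
        exp(config$marker_log_fold_change)
      subtypes[j] <- marker_type[g]
    }
    subtypes[classes == "noise"] <- "flat"
    libsize <- exp(stats::rnorm(n, 0, config$libsize_sigma))
    counts <- matrix(stats::rnbinom(n * n_genes,
                                    mu = libsize * mu,
                                    size = config$nb_dispersion),
                     nrow = n, ncol = n_genes,
                     dimnames = dimnames(mu))
    list(matrix = expression_matrix(counts, truth$cell_ids, gene_ids,
                                    layer = "raw"),
         gene_class = data.frame(gene_id = gene_ids, class = classes,
                                 subtype = subtypes,
                                 stringsAsFactors = FALSE),
         mu = mu, libsize = libsize)
  })
}

#' Generate a complete synthetic dataset
#'
#' Composes [generate_tissue()], [assign_cell_types()] and
#' [generate_expression()]. Deterministic under the config seed.
#'
#' @param config a [synthetic_config()].
#' @return An object of class `synthetic_dataset`: list with `matrix`,
#'   `coords`, `truth`, `gene_class`, `mu`, `libsize`, `domains`,
#'   `config`.
#' @export
generate_dataset <- function(config = synthetic_config()) {
  tissue <- generate_tissue(config)
  truth <- assign_cell_types(tissue$domains, config,
                             cell_ids = tissue$coords$cell_ids)
  expr <- generate_expression(truth, tissue$coords, config)
  structure(list(matrix = expr$matrix, coords = tissue$coords,
                 truth = truth, gene_class = expr$gene_class,
                 mu = expr$mu, libsize = expr$libsize,
                 domains = tissue$domains, config = config),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "synthetic_dataset: %d cells, %d genes (%d sv / %d hv / %d noise), %d types\n",
    length(x$coords$cell_ids), length(x$matrix$gene_ids),
    x$config$n_sv_genes, x$config$n_hv_genes, x$config$n_noise_genes,
    nlevels(x$truth$labels)))
  invisible(x)
}

#' Write a synthetic dataset to a directory
#'
#' Emits `matrix.mtx` + `genes.txt` + `cells.txt`, `coords.csv`,
#' `labels.csv` and `gene_class.csv` in io-module formats.
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_counts(dataset$matrix, file.path(dir, "matrix.mtx"),
               format = "mtx_triplet")
  write_coords(dataset$coords, file.path(dir, "coords.csv"))
  write_labels(dataset$truth, file.path(dir, "labels.csv"))
  utils::write.csv(dataset$gene_class, file.path(dir, "gene_class.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}
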