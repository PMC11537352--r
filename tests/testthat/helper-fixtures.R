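# Shared fixtures, all built in code.

# Small raw expression matrix with named cells/genes.
tiny_matrix <- function(values, layer = "raw") {
  values <- as.matrix(values)
  expression_matrix(values,
                    cell_ids = sprintf("c%d", seq_len(nrow(values))),
                    gene_ids = sprintf("g%d", seq_len(ncol(values))),
                    layer = layer)
}

# A fast, small synthetic config for tests that only need structure.
tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(n_cells = 150, n_domains = 3, n_localized_types = 3,
                   n_dispersed_types = 2, n_sv_genes = 12,
                   n_hv_genes = 12, n_noise_genes = 16, seed = 1)
  if (!is.null(args$n_domains) && is.null(args$n_localized_types))
    defaults$n_localized_types <- args$n_domains
  do.call(synthetic_config, utils::modifyList(defaults, args))
}

# Gaussian blob embedding: k blobs of n_per cells each, separated both
# in location (euclidean) and in row profile (correlation distances):
# blob i loads on coordinate pair (2i-1, 2i).
blob_embedding <- function(k = 3, n_per = 100, sep = 20, dim = NULL,
                           seed = 1) {
  if (is.null(dim)) dim <- max(2 * k, 4)
  set.seed(seed)
  centers <- matrix(0, k, dim)
  for (i in seq_len(k)) centers[i, c(2 * i - 1, 2 * i)] <- sep
  x <- do.call(rbind, lapply(seq_len(k), function(i) {
    matrix(stats::rnorm(n_per * dim), n_per, dim) +
      matrix(centers[i, ], n_per, dim, byrow = TRUE)
  }))
  list(structure(list(cell_ids = sprintf("c%d", seq_len(k * n_per)),
                      coordinates = x, n_pcs = dim, sdev = rep(1, dim),
                      selection = list(source = "all", level = "low",
                                       n_genes = dim)),
                 class = "embedding"),
       rep(seq_len(k), each = n_per))
}

# Independent brute-force spatial concordance evaluator: recomputes
# neighbourhoods, entropies and the weighted match sum from first
# principles with plain loops.
brute_force_sc <- function(u, u_star, x, y, k_spatial) {
  n <- length(u)
  e <- numeric(n)
  nbs <- vector("list", n)
  for (i in seq_len(n)) {
    d <- sqrt((x - x[i])^2 + (y - y[i])^2)
    ord <- order(d, seq_len(n))
    nb <- c(i, ord[ord != i][seq_len(k_spatial)])  # self + k nearest
    nbs[[i]] <- nb
    tab <- table(u[nb])
    p <- tab / sum(tab)
    e[i] <- -sum(ifelse(p > 0, p * log(p), 0))
  }
  w <- if (sum(e) == 0) rep(1 / n, n) else e / sum(e)
  sum(w[u == u_star])
}
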