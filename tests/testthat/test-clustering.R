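# PCA, sNN graph, Leiden tuning, kmeans variants, profile matching.

test_that("PCA embedding matches eigendecomposition and is deterministic", {
  set.seed(21)
  x <- matrix(rnorm(200 * 8), 200, 8) %*% diag(c(4, 3, 2, 1, rep(0.5, 4)))
  em <- tiny_matrix(x, layer = "pearson")
  sel <- gene_selection("all", "low", em$gene_ids)
  emb <- compute_pca(em, sel, n_pcs = 5)
  expect_identical(emb$n_pcs, 5L)
  # oracle: explained variances equal covariance eigenvalues
  ev <- eigen(stats::cov(x), symmetric = TRUE)$values
  expect_equal(emb$sdev^2, ev[1:5], tolerance = 1e-8)
  # scores equal centred data projected on eigenvectors (up to sign)
  expect_equal(abs(stats::cor(emb$coordinates[, 1],
                              scale(x, scale = FALSE) %*%
                                eigen(stats::cov(x))$vectors[, 1])[1]),
               1, tolerance = 1e-8)
  # two perfectly correlated genes: PC1 explains ~everything
  y <- cbind(rnorm(100), 0)
  y[, 2] <- 2 * y[, 1]
  em2 <- tiny_matrix(y, layer = "pearson")
  emb2 <- compute_pca(em2, gene_selection("all", "low", em2$gene_ids))
  expect_gt(emb2$sdev[1]^2 / sum(emb2$sdev^2), 0.999)
  # determinism incl. the sign convention
  emb3 <- compute_pca(em, sel, n_pcs = 5)
  expect_identical(emb$coordinates, emb3$coordinates)
  expect_error(compute_pca(em, gene_selection("hv", "low", character(0))),
               "empty")
})

test_that("sNN weights are Jaccard overlaps with pruned zero edges", {
  # a and b share an identical 2-NN set without being neighbours
  pts <- rbind(c(0, 0), c(3, 0), c(1.5, 1), c(1.5, 1.01))
  emb <- structure(list(cell_ids = c("a", "b", "c", "d"),
                        coordinates = pts),
                   class = "embedding")
  g <- build_snn(emb, k_neighbors = 2)
  w <- igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE)
  expect_equal(w["a", "b"], 1)           # identical kNN sets
  expect_equal(w, t(w))                  # symmetric
  expect_true(all(w >= 0 & w <= 1))
  # two far blobs with k = 15: no cross-blob edges
  be <- blob_embedding(k = 2, n_per = 20, sep = 100)
  g2 <- build_snn(be[[1]], k_neighbors = 15)
  w2 <- igraph::as_adjacency_matrix(g2, attr = "weight", sparse = FALSE)
  expect_true(all(w2[1:20, 21:40] == 0))
  expect_error(build_snn(emb, k_neighbors = 10), "k_neighbors")
})

test_that("tuned Leiden recovers well-separated blobs exactly", {
  be <- blob_embedding(k = 3, n_per = 100, sep = 20)
  g <- build_snn(be[[1]], k_neighbors = 15)
  res <- leiden_tuned(g, target_k = 3)
  expect_identical(res$n_clusters, 3L)
  expect_gte(res$params$n_hits, 8)
  expect_equal(ami(res$cluster_labels, be[[2]]), 1)
  # determinism
  res2 <- leiden_tuned(g, target_k = 3)
  expect_identical(as.character(res$cluster_labels),
                   as.character(res2$cluster_labels))
  expect_identical(res$params$resolution, res2$params$resolution)
  expect_error(leiden_tuned(g, target_k = 1), "target_k")
})

test_that("kmeans distances behave as specified", {
  be <- blob_embedding(k = 2, n_per = 40, sep = 30)
  emb <- be[[1]]
  for (d in c("euclidean", "pearson", "spearman")) {
    res <- kmeans_cluster(emb, k = 2, distance = d, seed = 1)
    expect_equal(ami(res$cluster_labels, be[[2]]), 1, tolerance = 1e-12,
                 label = d)
  }
  # k = n: every cell its own cluster
  small <- structure(list(cell_ids = sprintf("c%d", 1:5),
                          coordinates = matrix(rnorm(10), 5, 2)),
                     class = "embedding")
  res_n <- kmeans_cluster(small, k = 5, seed = 1)
  expect_identical(res_n$n_clusters, 5L)
  expect_error(kmeans_cluster(small, k = 6), "exceeds")
  # pearson distance invariant to per-cell affine rescaling
  emb_t <- emb
  emb_t$coordinates <- emb$coordinates * 3 + 7
  r1 <- kmeans_cluster(emb, k = 2, distance = "pearson", seed = 2)
  r2 <- kmeans_cluster(emb_t, k = 2, distance = "pearson", seed = 2)
  expect_equal(adjusted_rand(r1$cluster_labels, r2$cluster_labels), 1)
})

test_that("profile matching maps clusters onto the truth vocabulary", {
  set.seed(5)
  # 3 classes with distinct profiles over 6 genes
  n_per <- 30
  profs <- rbind(c(10, 1, 1, 5, 1, 1), c(1, 10, 1, 1, 5, 1),
                 c(1, 1, 10, 1, 1, 5))
  x <- do.call(rbind, lapply(1:3, function(i)
    matrix(rpois(n_per * 6, rep(profs[i, ], each = n_per)), n_per, 6)))
  em <- tiny_matrix(x)
  truth <- label_set(em$cell_ids, rep(c("T1", "T2", "T3"), each = n_per))
  sel <- gene_selection("all", "low", em$gene_ids)
  # predicted clusters = truth with permuted arbitrary ids
  pred <- structure(list(cell_ids = em$cell_ids,
                         cluster_labels = factor(rep(c("k7", "k2", "k9"),
                                                     each = n_per)),
                         method = "leiden", params = list(),
                         n_clusters = 3L),
                    class = "clustering_result")
  m <- match_labels(pred, truth, em, sel)
  expect_identical(as.character(m$u_star), as.character(m$u))
  expect_equal(ami(m$u, m$u_star), 1)
  # permuting predicted cluster ids leaves u_star unchanged
  relab <- c(k7 = "z1", k2 = "z2", k9 = "z3")
  pred2 <- pred
  pred2$cluster_labels <- factor(relab[as.character(pred$cluster_labels)])
  m2 <- match_labels(pred2, truth, em, sel)
  expect_identical(as.character(m2$u_star), as.character(m$u_star))
})

test_that("optimal assignment beats greedy row-wise matching", {
  # correlation matrix where greedy assigns both clusters to class 1
  score <- rbind(c(0.9, 0.8), c(0.85, 0.1))
  a <- svhvbench:::solve_assignment_max(score)
  expect_identical(a, c(2L, 1L))  # total 0.8 + 0.85 > 0.9 + 0.1
  # brute-force oracle over random square problems
  set.seed(6)
  perms <- function(n) {
    if (n == 1) return(matrix(1))
    p <- perms(n - 1)
    do.call(rbind, lapply(seq_len(n), function(i) {
      cbind(i, matrix(c(seq_len(n)[-i])[p], nrow(p))) }))
  }
  for (n in 2:5) {
    pm <- perms(n)
    for (rep in 1:10) {
      s <- matrix(rnorm(n * n), n)
      best <- max(apply(pm, 1, function(p) sum(s[cbind(1:n, p)])))
      got <- sum(s[cbind(1:n, svhvbench:::solve_assignment_max(s))])
      expect_equal(got, best, tolerance = 1e-9)
    }
  }
})

test_that("swapped profiles are resolved by the optimal assignment", {
  set.seed(8)
  # two clusters whose best greedy match collides; enumeration oracle
  n_per <- 25
  profs <- rbind(c(8, 6, 1), c(6, 8, 1))
  x <- do.call(rbind, lapply(1:2, function(i)
    matrix(rpois(n_per * 3, rep(profs[i, ], each = n_per)), n_per, 3)))
  em <- tiny_matrix(x)
  truth <- label_set(em$cell_ids, rep(c("A", "B"), each = n_per))
  pred <- structure(list(cell_ids = em$cell_ids,
                         cluster_labels = factor(rep(c("c1", "c2"),
                                                     each = n_per)),
                         method = "kmeans", params = list(),
                         n_clusters = 2L),
                    class = "clustering_result")
  m <- match_labels(pred, truth, em,
                    gene_selection("all", "low", em$gene_ids))
  expect_identical(sort(unique(as.character(m$u_star))), c("A", "B"))
  expect_identical(as.character(m$u_star), as.character(m$u))
})

test_that("the composed chain recovers synthetic types end-to-end", {
  # marker-dominant tissue: every type carries a strong expression
  # signature, so the chain should recover types almost perfectly
  cfg <- tiny_config(n_cells = 300, n_domains = 3, n_localized_types = 3,
                     n_dispersed_types = 2, dispersed_fraction = 0.2,
                     n_hv_genes = 25, n_sv_genes = 4, sv_amplitude = 0.4,
                     marker_log_fold_change = 2.5, seed = 13)
  ds <- generate_dataset(cfg)
  prep <- preprocess_pipeline(ds$matrix, ds$truth)
  sel <- gene_selection("all", "low", prep$matrix$gene_ids)
  emb <- compute_pca(prep$matrix, sel)
  cl <- leiden_tuned(build_snn(emb), target_k = nlevels(prep$truth$labels))
  m <- match_labels(cl, prep$truth, prep$matrix, sel)
  expect_gte(ami(m$u, m$u_star), 0.95)
})
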