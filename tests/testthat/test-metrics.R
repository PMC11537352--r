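# Metric correctness: frozen oracle values, hand-computed instances,
# brute-force equivalence, bounds and invariances.

matched <- function(u, u_star, cell_ids = sprintf("c%d", seq_along(u))) {
  lev <- unique(c(u, u_star))
  structure(list(u = factor(u, levels = lev),
                 u_star = factor(u_star, levels = lev),
                 cell_ids = cell_ids, mapping = NULL),
            class = "matched_labels")
}

test_that("AMI reproduces reference values and conventions", {
  # values frozen from an independent reference implementation
  expect_equal(ami(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5, tolerance = 1e-10)
  expect_equal(ami(c("A", "A", "B", "B"), c("A", "A", "B", "C")),
               0.5714285714, tolerance = 1e-9)
  expect_equal(ami(c(1, 1, 1, 2, 2), c(1, 1, 2, 2, 2)),
               0.2512669357, tolerance = 1e-9)
  expect_equal(ami(c(0, 0, 1, 1, 2, 2, 2), c(0, 1, 1, 2, 2, 2, 0)),
               -0.0538852035, tolerance = 1e-9)
  # identity and relabelling invariance
  expect_equal(ami(c(1, 2, 2, 3), c(1, 2, 2, 3)), 1)
  expect_equal(ami(c(1, 2, 2, 3), c("x", "y", "y", "z")), 1)
  expect_equal(ami(c(1, 2, 3), c(7, 8, 9)), 1)   # identical singletons
  expect_equal(ami(c(1, 1, 1), c(2, 2, 2)), 1)   # identical single class
  expect_error(ami(1:4, 1:3), "length")
})

test_that("AMI matches a Monte-Carlo expected-MI oracle", {
  # independent route: estimate E[MI] by averaging MI over random
  # permutations instead of the hypergeometric closed form
  mi_nat <- function(u, v) {
    tab <- table(u, v); n <- sum(tab)
    a <- rowSums(tab); b <- colSums(tab); nz <- tab > 0
    sum((tab[nz] / n) * log(n * tab[nz] / outer(a, b)[nz]))
  }
  set.seed(33)
  for (rep in 1:5) {
    u <- sample(letters[1:3], 40, replace = TRUE)
    v <- sample(letters[1:4], 40, replace = TRUE)
    hu <- svhvbench:::entropy_nat(table(u))
    hv <- svhvbench:::entropy_nat(table(v))
    emi_mc <- mean(vapply(1:4000, function(i) mi_nat(u, sample(v)),
                          numeric(1)))
    oracle <- (mi_nat(u, v) - emi_mc) / ((hu + hv) / 2 - emi_mc)
    expect_equal(ami(u, v), oracle, tolerance = 0.05)
  }
})

test_that("weighted F1 reproduces the hand-computed instance", {
  expect_equal(weighted_f1(matched(c("A", "A", "B", "B", "B"),
                                   c("A", "A", "A", "B", "B"))), 0.8)
  u <- c("A", "A", "B", "B")
  expect_equal(weighted_f1(matched(u, u)), 1)
  # a class never predicted scores F1 = 0 and drags the mean below 1
  m <- matched(c("A", "A", "B"), c("A", "A", "A"))
  expect_lt(weighted_f1(m), 1)
  expect_equal(weighted_f1(m), (2 / 3) * (4 / 5) + (1 / 3) * 0)
})

test_that("Pearson Gamma reproduces the printed 4-point instance", {
  x <- matrix(c(0, 0.1, 10, 10.1), ncol = 1)
  g <- pearson_gamma(c("a", "a", "b", "b"), x)
  expect_equal(g, 0.99990, tolerance = 1e-4)
  expect_warning(g1 <- pearson_gamma(rep("a", 4), x), "single cluster")
  expect_true(is.nan(g1))
  # random labels on uniform points give |gamma| near 0
  ok <- vapply(1:100, function(s) {
    set.seed(s)
    pts <- matrix(runif(200), ncol = 1)
    abs(pearson_gamma(sample(rep(c("a", "b"), 100)), pts)) < 0.1
  }, logical(1))
  expect_gte(mean(ok), 0.95)
  # subsampling cap: deterministic under seed
  set.seed(1)
  big <- matrix(rnorm(3000), ncol = 1)
  lab <- rep(c("a", "b"), length.out = 3000)
  expect_equal(pearson_gamma(lab, big, subsample_cap = 500, seed = 3),
               pearson_gamma(lab, big, subsample_cap = 500, seed = 3))
})

test_that("spatial neighbourhoods are kNN with self and index ties", {
  co <- spatial_coords(c("a", "b", "c", "d"), c(0, 1, 2.5, 3.5),
                       rep(0, 4))
  nb <- build_neighborhoods(co, k_spatial = 1)
  expect_identical(lapply(nb$members, sort),
                   list(c(1L, 2L), c(1L, 2L), c(3L, 4L), c(3L, 4L)))
  expect_true(all(vapply(seq_along(nb$members),
                         function(i) i %in% nb$members[[i]], logical(1))))
  expect_error(build_neighborhoods(co, k_spatial = 4), "k_spatial")
  # order invariance: permuting input, neighbourhoods map back
  perm <- c(3, 1, 4, 2)
  co2 <- spatial_coords(co$cell_ids[perm], co$x[perm], co$y[perm])
  nb2 <- build_neighborhoods(co2, k_spatial = 1)
  named <- function(nb, co) sort(vapply(nb$members, function(m)
    paste(sort(co$cell_ids[m]), collapse = "|"), character(1)))
  expect_identical(named(nb2, co2), named(nb, co))
})

test_that("entropy weights reproduce the worked 4-point instance", {
  co <- spatial_coords(c("a", "b", "c", "d"), c(0, 1, 2.1, 3.0),
                       rep(0, 4))
  nb <- build_neighborhoods(co, k_spatial = 1)
  truth <- c("A", "B", "B", "B")
  w <- entropy_weights(truth, nb)
  expect_equal(w$e, c(log(2), log(2), 0, 0))
  expect_equal(w$w, c(0.5, 0.5, 0, 0))
  expect_equal(sum(w$w), 1)
  # all one label: zero entropies fall back to uniform weights
  w0 <- entropy_weights(rep("A", 4), nb)
  expect_equal(w0$w, rep(0.25, 4))
})

test_that("spatial concordance matches the hand instance and conventions", {
  co <- spatial_coords(c("a", "b", "c", "d"), c(0, 1, 2.1, 3.0),
                       rep(0, 4))
  nb <- build_neighborhoods(co, k_spatial = 1)
  u <- c("A", "B", "B", "B"); us <- c("A", "A", "B", "B")
  w <- entropy_weights(u, nb)
  expect_equal(spatial_concordance(matched(u, us), w), 0.5)
  expect_equal(spatial_concordance(matched(u, u), w), 1)
  # mean spatial AMI on the same instance is 0 (mismatched border
  # neighbourhoods carry all the weight)
  expect_equal(mean_spatial_ami(matched(u, us), nb, w), 0)
  expect_equal(mean_spatial_ami(matched(u, u), nb, w), 1)
  # relabelling u_star consistently leaves both metrics unchanged
  us2 <- c("Z", "Z", "Y", "Y")  # same partition as us
  m1 <- matched(u, us); m2 <- matched(u, us2)
  expect_equal(mean_spatial_ami(m2, nb, w), mean_spatial_ami(m1, nb, w))
})

test_that("spatial concordance equals brute force on all 6-cell labelings", {
  set.seed(99)
  x <- runif(6); y <- runif(6)
  co <- spatial_coords(sprintf("c%d", 1:6), x, y)
  nb <- build_neighborhoods(co, k_spatial = 2)
  grids <- as.matrix(expand.grid(rep(list(c("A", "B")), 6)))
  for (i in seq_len(nrow(grids))) {
    u <- grids[i, ]
    w <- entropy_weights(u, nb)
    for (j in seq(1, nrow(grids), by = 16)) {  # stride over predictions
      us <- grids[j, ]
      expect_equal(spatial_concordance(matched(u, us), w),
                   brute_force_sc(u, us, x, y, 2), tolerance = 1e-12)
    }
  }
})

test_that("bounded metrics stay in range on fuzzed inputs", {
  set.seed(17)
  for (i in 1:200) {
    n <- sample(8:40, 1)
    co <- spatial_coords(sprintf("c%d", 1:n), runif(n), runif(n))
    k <- sample(1:5, 1)
    nb <- build_neighborhoods(co, k_spatial = k)
    u <- sample(letters[1:sample(2:4, 1)], n, replace = TRUE)
    us <- sample(letters[1:4], n, replace = TRUE)
    m <- matched(u, us)
    w <- entropy_weights(u, nb)
    a <- ami(u, us)
    expect_lte(a, 1)
    expect_true(weighted_f1(m) >= 0 && weighted_f1(m) <= 1)
    sc <- spatial_concordance(m, w)
    expect_true(sc >= 0 && sc <= 1 + 1e-12)
    ms <- mean_spatial_ami(m, nb, w)
    expect_true(ms >= 0 && ms <= 1)
  }
})

test_that("evaluate_all composes the five metrics consistently", {
  cfg <- tiny_config(n_cells = 80, seed = 3)
  ds <- generate_dataset(cfg)
  sel <- gene_selection("all", "low", ds$matrix$gene_ids)
  emb <- compute_pca(pearson_residuals(ds$matrix), sel, n_pcs = 10)
  pred <- structure(list(cell_ids = ds$matrix$cell_ids,
                         cluster_labels = ds$truth$labels,
                         method = "leiden", params = list(),
                         n_clusters = nlevels(ds$truth$labels)),
                    class = "clustering_result")
  m <- match_labels(pred, ds$truth, pearson_residuals(ds$matrix), sel)
  rec <- evaluate_all(m, emb, ds$coords, config = list(k_spatial = 10),
                      dataset = "toy")
  expect_identical(nrow(rec), 5L)
  expect_setequal(rec$metric, c("ami", "weighted_f1", "pearson_gamma",
                                "spatial_concordance",
                                "mean_spatial_ami"))
  perfect <- rec$metric != "pearson_gamma"
  expect_equal(rec$value[perfect], rep(1, 4))
  expect_gt(rec$value[rec$metric == "pearson_gamma"], 0)
  # values equal the operations called directly
  nb <- build_neighborhoods(align_to_matrix(ds$matrix, ds$coords),
                            k_spatial = 10)
  w <- entropy_weights(m$u, nb)
  expect_equal(rec$value[rec$metric == "spatial_concordance"],
               spatial_concordance(m, w))
  expect_equal(rec$value[rec$metric == "mean_spatial_ami"],
               mean_spatial_ami(m, nb, w))
})
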