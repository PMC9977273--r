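# Normalization, variable genes, scaling with covariate regression, PCA,
# SNN graph and Louvain clustering.

test_that("log normalization matches its closed form", {
  m <- toy_matrix(matrix(c(1, 0, 3), 1, 3))
  nm <- log_normalize(m, scale_factor = 1e4)
  expect_equal(as.numeric(nm$values[1, ]),
               c(log(2501), 0, log(7501)))
})

test_that("all-equal counts normalize to one shared value", {
  m <- toy_matrix(matrix(5, 3, 8))
  nm <- log_normalize(m)
  expect_true(all(abs(nm$values@x - log(1 + 1e4 / 8)) < 1e-12))
})

test_that("normalization is invariant to per-cell count scaling", {
  withr::local_seed(3)
  counts <- matrix(rpois(40, 5) + 1, 4, 10)
  nm1 <- log_normalize(toy_matrix(counts))
  nm2 <- log_normalize(toy_matrix(counts * 2))
  expect_equal(as.matrix(nm1$values), as.matrix(nm2$values))
})

test_that("normalized cells conserve the scale factor", {
  cfg <- cluster_recovery_config(seed = 2)
  sim <- simulate_hto(cfg)
  expr <- simulate_expression(cfg, sim$truth)
  nm <- log_normalize(expr)
  recon <- Matrix::rowSums(expm1(nm$values))
  expect_true(all(abs(recon - 1e4) / 1e4 < 1e-6))
  m0 <- toy_matrix(rbind(c(0, 0), c(1, 2)))
  expect_error(log_normalize(m0), "zero-total")
})

test_that("variable-gene ranking puts constant genes last, ties by id", {
  withr::local_seed(4)
  counts <- cbind(matrix(rpois(50 * 3, 10), 50, 3), 7, 7)
  m <- toy_matrix(counts, feature_names = c("v1", "v2", "v3", "flatB", "flatA"))
  nm <- log_normalize(m)
  ranked <- select_variable_genes(nm, 5)
  expect_setequal(ranked[4:5], c("flatA", "flatB"))
  expect_equal(ranked[4:5], c("flatA", "flatB")) # deterministic tie order
  expect_error(select_variable_genes(nm, 6), "exceeds gene count")
})

test_that("planted high-dispersion markers rank among the top genes", {
  spec <- list(a = list(freq = c(treg_depleted = 0.5, control = 0.5),
                        markers = sprintf("Gene%04d", 1:20), log2fc = 3),
               b = list(freq = c(treg_depleted = 0.5, control = 0.5),
                        markers = character(0), log2fc = 0))
  cfg <- synth_config(n_samples = 2, cells_per_sample = 400, doublet_rate = 0,
                      n_genes = 2000, cluster_spec = spec,
                      program_spec = list(genes = "Gene0100",
                                          effect = c(treg_depleted = 0,
                                                     control = 0)),
                      seed = 1)
  sim <- simulate_hto(cfg)
  expr <- simulate_expression(cfg, sim$truth)
  nm <- log_normalize(expr)
  top <- select_variable_genes(nm, 100)
  expect_true(all(sprintf("Gene%04d", 1:20) %in% top))
})

test_that("scaling standardizes residuals after covariate regression", {
  withr::local_seed(6)
  y <- rnorm(30)
  x <- rnorm(30)
  x_orth <- residuals(lm(x ~ y))
  nm <- toy_normalized(cbind(g1 = y, g2 = y))
  # covariate orthogonal to expression: residual z-scores = plain z-scores
  s_cov <- scale_and_regress(nm, c("g1", "g2"), covariates = cbind(x_orth))
  s_plain <- scale_and_regress(nm, c("g1", "g2"))
  expect_equal(s_cov, s_plain, tolerance = 1e-10)
  # expression equal to a covariate: gene reported constant (all zero)
  s_self <- scale_and_regress(nm, "g1", covariates = cbind(y))
  expect_true(all(s_self == 0))
})

test_that("exact least squares on a 3-cell toy gives zero residuals", {
  nm <- toy_normalized(cbind(g1 = c(1, 2, 3)))
  out <- scale_and_regress(nm, "g1", covariates = cbind(x = c(1, 2, 3)))
  expect_true(all(out == 0))
})

test_that("collinear covariates are dropped with a warning and values clip", {
  withr::local_seed(7)
  nm <- toy_normalized(matrix(rnorm(60), 20, 3))
  x <- rnorm(20)
  expect_warning(scale_and_regress(nm, nm$genes,
                                   covariates = cbind(a = x, b = 2 * x)),
                 "collinear")
  vals <- c(rnorm(19), 100)
  out <- scale_and_regress(toy_normalized(cbind(g1 = vals)), "g1", clip = 2)
  expect_lte(max(abs(out)), 2)
})

test_that("PCA finds the separating axis and conserves variance", {
  withr::local_seed(8)
  pts <- rbind(cbind(rnorm(40, -5, 0.3), rnorm(40, 0, 0.3)),
               cbind(rnorm(40, 5, 0.3), rnorm(40, 0, 0.3)))
  emb <- pca_embed(pts, 2)
  sdev <- attr(emb, "sdev")
  expect_gt(sdev[1]^2 / sum(sdev^2), 0.9)
  expect_lte(sum(sdev^2), sum(apply(pts, 2, var)) + 1e-8)
  expect_true(all(diff(sdev) <= 1e-10)) # non-increasing
  # duplicated rows embed identically
  emb2 <- pca_embed(rbind(pts, pts[1, , drop = FALSE]), 2)
  expect_equal(unname(emb2[81, ]), unname(emb2[1, ]))
  expect_error(pca_embed(pts, 3), "n_pcs")
})

test_that("PCA is deterministic with the fixed sign convention", {
  withr::local_seed(9)
  x <- matrix(rnorm(200), 20, 10)
  e1 <- pca_embed(x, 4)
  e2 <- pca_embed(x, 4)
  expect_identical(e1, e2)
  rot <- attr(e1, "rotation")
  for (j in 1:4) expect_gt(rot[which.max(abs(rot[, j])), j], 0)
  # wide case (genes > cells) agrees with the tall path
  xw <- matrix(rnorm(5 * 30), 5, 30)
  ew <- pca_embed(xw, 3)
  sv <- svd(sweep(xw, 2, colMeans(xw)))
  expect_equal(abs(unname(ew)), abs(sv$u[, 1:3] %*% diag(sv$d[1:3])),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("three mutually equidistant points at k=2 form a complete unit-weight graph", {
  pts <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  g <- snn_graph(pts, k_neighbors = 2, prune = 1 / 15)
  expect_equal(igraph::ecount(g), 3)
  expect_true(all(igraph::E(g)$weight == 1))
})

test_that("far-separated clusters get no cross edges and Jaccard stays in (0,1]", {
  withr::local_seed(10)
  pts <- rbind(matrix(rnorm(40, 0, 0.1), 20, 2),
               matrix(rnorm(40, 100, 0.1), 20, 2))
  g <- snn_graph(pts, k_neighbors = 5)
  ends <- igraph::as_edgelist(g, names = FALSE)
  expect_true(all((ends[, 1] <= 20) == (ends[, 2] <= 20)))
  w <- igraph::E(g)$weight
  expect_true(all(w > 0 & w <= 1))
  expect_error(snn_graph(pts[1:3, ], k_neighbors = 3), "smaller than")
})

test_that("Louvain separates components and merges complete graphs", {
  two_tri <- igraph::graph_from_edgelist(
    rbind(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6)),
    directed = FALSE)
  lab <- louvain_cluster(two_tri, resolution = 1, seed = 1)
  expect_equal(length(unique(lab)), 2)
  expect_equal(lab[1], lab[2])
  expect_false(lab[1] == lab[4])

  k4 <- igraph::make_full_graph(4)
  expect_equal(length(unique(louvain_cluster(k4, resolution = 1, seed = 1))), 1)

  empty <- igraph::make_empty_graph(3, directed = FALSE)
  expect_warning(lab0 <- louvain_cluster(empty, 1, 1), "no edges")
  expect_equal(length(unique(lab0)), 3)
})

test_that("the returned partition beats the one-cluster partition's modularity", {
  withr::local_seed(11)
  g <- igraph::sample_gnp(30, 0.15)
  lab <- louvain_cluster(g, resolution = 1, seed = 1)
  expect_gte(partition_modularity(g, lab, 1),
             partition_modularity(g, rep(1, 30), 1))
})

test_that("greedy Louvain is suboptimal on an 8-cycle (documented limitation)", {
  g <- igraph::make_ring(8)
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  lab <- louvain_cluster(g, resolution = 1, seed = 1)
  greedy <- oracle_modularity(A, lab, 1)
  best <- oracle_best_modularity(A, 1)
  expect_equal(greedy, 0.25, tolerance = 1e-10)
  expect_equal(best, 0.28125, tolerance = 1e-10)
  expect_lt(greedy, best)
})

test_that("the packaged ARI agrees with the external reference", {
  withr::local_seed(14)
  for (i in 1:5) {
    a <- sample(1:4, 60, replace = TRUE)
    b <- sample(1:3, 60, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b))
  }
  expect_equal(adjusted_rand_index(1:10, 1:10), 1)
})

test_that("the full reduction path is deterministic given a seed", {
  cfg <- cluster_recovery_config(seed = 3)
  sim <- simulate_hto(cfg)
  expr <- simulate_expression(cfg, sim$truth)
  nm <- log_normalize(expr)
  hvg <- select_variable_genes(nm, 40)
  run_once <- function() {
    emb <- pca_embed(scale_and_regress(nm, hvg), 10)
    louvain_cluster(snn_graph(emb, 15), resolution = 0.8, seed = 1)
  }
  expect_identical(run_once(), run_once())
})
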