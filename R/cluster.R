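# PCA embedding, shared-nearest-neighbor graph and Louvain clustering.
# kNN search is exact (brute-force Euclidean) and the SNN edge weight is
# the Jaccard overlap of neighborhoods (self included), pruned at 1/15 by
# convention; community detection delegates to igraph's
# resolution-parameterised Louvain.

#' Deterministic PCA embedding
#'
#' Exact PCA via an eigendecomposition of the smaller of the two Gram
#' matrices. Signs are fixed by making each component's
#' largest-magnitude loading positive, so embeddings are reproducible
#' across runs and platforms.
#'
#' @param scaled dense cells x genes matrix (from [scale_and_regress()]).
#' @param n_pcs number of components (<= min(cells, genes)).
#' @return cells x n_pcs score matrix with attributes `sdev` (component
#'   standard deviations) and `rotation`.
#' @export
pca_embed <- function(scaled, n_pcs) {
  n <- nrow(scaled)
  p <- ncol(scaled)
  if (n_pcs > min(n, p))
    stop("parameter error: n_pcs (", n_pcs, ") exceeds min(cells, genes) = ",
         min(n, p), call. = FALSE)
  X <- sweep(scaled, 2, colMeans(scaled))
  if (p <= n) {
    eig <- eigen(crossprod(X) / (n - 1), symmetric = TRUE)
    rot <- eig$vectors[, seq_len(n_pcs), drop = FALSE]
    scores <- X %*% rot
  } else {
    eig <- eigen(tcrossprod(X) / (n - 1), symmetric = TRUE)
    scores <- eig$vectors[, seq_len(n_pcs), drop = FALSE] %*%
      diag(sqrt(pmax(eig$values[seq_len(n_pcs)], 0) * (n - 1)), n_pcs)
    rot <- crossprod(X, scores)
    rot <- sweep(rot, 2, sqrt(colSums(rot^2)), "/")
  }
  # sign convention: largest-magnitude loading positive
  for (j in seq_len(n_pcs)) {
    k <- which.max(abs(rot[, j]))
    if (rot[k, j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  sdev <- sqrt(pmax(eig$values, 0))
  dimnames(scores) <- list(rownames(scaled), paste0("PC", seq_len(n_pcs)))
  attr(scores, "sdev") <- sdev
  attr(scores, "rotation") <- rot
  scores
}

# exact k nearest neighbors (excluding self), brute force, block-wise
.knn_exact <- function(emb, k) {
  n <- nrow(emb)
  idx <- matrix(0L, n, k)
  sq <- rowSums(emb^2)
  block <- max(1L, floor(2e7 / n))
  for (s in seq(1L, n, by = block)) {
    rows <- s:min(s + block - 1L, n)
    d2 <- outer(sq[rows], sq, "+") - 2 * tcrossprod(emb[rows, , drop = FALSE], emb)
    for (i in seq_along(rows)) {
      d <- d2[i, ]
      d[rows[i]] <- Inf
      idx[rows[i], ] <- order(d)[seq_len(k)] # ties broken by index
    }
  }
  idx
}

#' Shared-nearest-neighbor graph in the embedding space
#'
#' Exact Euclidean k-nearest neighbors; each cell's neighborhood is
#' itself plus its `k_neighbors` nearest cells. Edge weight is the
#' Jaccard overlap of the two neighborhoods; weights at or below `prune`
#' are removed. The graph is undirected and weighted.
#'
#' @param embedding cells x PCs matrix.
#' @param k_neighbors neighborhood size excluding self (< cells).
#' @param prune Jaccard pruning threshold (default 1/15).
#' @return an `igraph` graph with `weight` edge attribute.
#' @export
snn_graph <- function(embedding, k_neighbors = 20, prune = 1/15) {
  n <- nrow(embedding)
  if (k_neighbors >= n)
    stop("parameter error: k_neighbors must be smaller than the number of cells",
         call. = FALSE)
  nn <- .knn_exact(embedding, k_neighbors)
  hood_size <- k_neighbors + 1L # self included
  A <- Matrix::sparseMatrix(
    i = rep(seq_len(n), hood_size),
    j = c(seq_len(n), as.vector(nn)),
    x = 1, dims = c(n, n)
  )
  shared <- Matrix::tcrossprod(A)
  shared <- as(shared, "CsparseMatrix")
  jac <- shared
  jac@x <- shared@x / (2 * hood_size - shared@x)
  jac@x[jac@x <= prune] <- 0
  jac <- Matrix::drop0(jac)
  Matrix::diag(jac) <- 0
  jac <- Matrix::drop0(jac)
  g <- igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                           weighted = TRUE)
  if (!is.null(rownames(embedding)))
    igraph::V(g)$name <- rownames(embedding)
  g
}

#' Louvain community detection with a resolution parameter
#'
#' Greedy multilevel maximization of resolution-parameterised modularity
#' (igraph's implementation), seeded for reproducibility. A graph with no
#' edges yields one cluster per node with a warning.
#'
#' @param graph weighted undirected `igraph` graph.
#' @param resolution resolution parameter (default 0.8; the re-analysis
#'   preset uses 0.3).
#' @param seed RNG seed for the (stochastic) vertex processing order.
#' @return integer cluster labels, named by vertex when names exist.
#' @export
louvain_cluster <- function(graph, resolution = 0.8, seed = 1) {
  if (igraph::vcount(graph) == 0) stop("empty graph", call. = FALSE)
  if (igraph::ecount(graph) == 0) {
    warning("graph has no edges; every node is its own cluster")
    labels <- seq_len(igraph::vcount(graph))
  } else {
    labels <- withr::with_seed(seed, {
      igraph::membership(igraph::cluster_louvain(graph, resolution = resolution))
    })
  }
  labels <- as.integer(labels)
  names(labels) <- igraph::V(graph)$name
  labels
}

#' Resolution-parameterised modularity of a partition
#'
#' Direct evaluation of
#' `Q = (1/2m) * sum_ij (A_ij - gamma * k_i * k_j / 2m) * [c_i == c_j]`
#' from the weighted adjacency matrix.
#'
#' @param graph weighted undirected `igraph` graph.
#' @param labels integer membership vector.
#' @param resolution gamma.
#' @return scalar modularity.
#' @export
partition_modularity <- function(graph, labels, resolution = 1) {
  A <- as.matrix(igraph::as_adjacency_matrix(graph, attr = if ("weight" %in%
    igraph::edge_attr_names(graph)) "weight" else NULL, sparse = TRUE))
  k <- rowSums(A)
  m2 <- sum(A)
  same <- outer(labels, labels, "==")
  sum((A - resolution * outer(k, k) / m2) * same) / m2
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement; 1 for identical partitions, ~0 for
#' independent ones.
#'
#' @param a,b label vectors of equal length.
#' @return scalar ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / ch2(n)
  denom <- (sum_a + sum_b) / 2 - expected
  if (denom == 0) return(1) # both partitions all-singletons: identical
  (sum_ij - expected) / denom
}
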