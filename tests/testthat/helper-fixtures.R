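# Shared fixtures and independent oracles, all built in code.

# small CountMatrix from a dense matrix; features named g1.. by default
toy_matrix <- function(counts, feature_names = NULL, feature_types = NULL,
                       barcodes = NULL) {
  counts <- as.matrix(counts)
  nf <- ncol(counts)
  if (is.null(feature_names)) feature_names <- paste0("g", seq_len(nf))
  if (is.null(feature_types)) feature_types <- rep("Gene Expression", nf)
  if (is.null(barcodes))
    barcodes <- as.character(sprintf("bc%d", seq_len(nrow(counts))))
  count_matrix(counts, barcodes,
               data.frame(id = feature_names, name = feature_names,
                          type = feature_types))
}

# fabricate a NormalizedMatrix directly from a dense log-expression matrix
toy_normalized <- function(values, genes = NULL, barcodes = NULL,
                           condition = NULL) {
  values <- as.matrix(values)
  if (is.null(genes)) genes <- paste0("g", seq_len(ncol(values)))
  if (is.null(barcodes)) barcodes <- paste0("bc", seq_len(nrow(values)))
  v <- Matrix::Matrix(values, sparse = TRUE)
  dimnames(v) <- list(barcodes, genes)
  structure(list(values = v, counts = Matrix::Matrix(expm1(values), sparse = TRUE),
                 genes = genes, barcodes = barcodes, scale_factor = 1e4,
                 condition = condition),
            class = "NormalizedMatrix")
}

# independent linear-scan oracle for the read limit: ascend from bin 0 to
# the first local maximum, then strictly descend
oracle_limit <- function(s) {
  i <- 1
  while (i < length(s) && s[i + 1] > s[i]) i <- i + 1
  while (i < length(s) && s[i + 1] < s[i]) i <- i + 1
  i - 1
}

# brute-force running-sum enrichment score
oracle_es <- function(stat, member, p = 1) {
  N <- length(stat)
  S <- sum(member)
  norm <- sum(abs(stat[member])^p)
  run <- 0
  best <- 0
  for (i in seq_len(N)) {
    run <- run + if (member[i]) {
      if (norm > 0) abs(stat[i])^p / norm else 1 / S
    } else -1 / (N - S)
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# hand-written resolution modularity from a (weighted) adjacency matrix
oracle_modularity <- function(A, labels, gamma = 1) {
  m2 <- sum(A)
  k <- rowSums(A)
  same <- outer(labels, labels, "==")
  sum((A - gamma * outer(k, k) / m2) * same) / m2
}

# all set partitions of n elements as restricted-growth label vectors
all_partitions <- function(n) {
  out <- list()
  rec <- function(labels, k) {
    i <- length(labels) + 1
    if (i > n) {
      out[[length(out) + 1]] <<- labels
      return(invisible())
    }
    for (c in seq_len(k + 1)) rec(c(labels, c), max(k, c))
  }
  rec(integer(0), 0L)
  out
}

# exhaustive modularity maximum over all partitions
oracle_best_modularity <- function(A, gamma = 1) {
  max(vapply(all_partitions(nrow(A)), function(p) oracle_modularity(A, p, gamma), 0))
}

# 3 well-separated planted clusters, 600 cells x 100 genes
cluster_recovery_config <- function(seed = 1) {
  spec3 <- list(
    a = list(freq = c(treg_depleted = 1/3, control = 1/3),
             markers = sprintf("Gene%04d", 1:10), log2fc = 2.5),
    b = list(freq = c(treg_depleted = 1/3, control = 1/3),
             markers = sprintf("Gene%04d", 11:20), log2fc = 2.5),
    c = list(freq = c(treg_depleted = 1/3, control = 1/3),
             markers = sprintf("Gene%04d", 21:30), log2fc = 2.5))
  synth_config(n_samples = 2, cells_per_sample = 300, doublet_rate = 0,
               n_genes = 100, cluster_spec = spec3,
               program_spec = list(genes = sprintf("Gene%04d", 31:35),
                                   effect = c(treg_depleted = 0, control = 0)),
               seed = seed)
}

# small but complete pipeline configuration for fast end-to-end tests
tiny_pipeline_config <- function(out_dir, seed = 1) {
  spec <- list(
    a = list(freq = c(treg_depleted = 0.5, control = 0.6),
             markers = sprintf("Gene%04d", 1:8), log2fc = 2.5),
    b = list(freq = c(treg_depleted = 0.3, control = 0.4),
             markers = sprintf("Gene%04d", 9:16), log2fc = 2.5),
    k = list(freq = c(treg_depleted = 0.2, control = 0.0),
             markers = sprintf("Gene%04d", 17:24), log2fc = 3))
  synth <- synth_config(n_samples = 2, cells_per_sample = 150,
                        doublet_rate = 0.05, n_genes = 120,
                        cluster_spec = spec,
                        program_spec = list(genes = sprintf("Gene%04d", 31:40),
                                            effect = c(treg_depleted = 1,
                                                       control = 0)),
                        seed = seed)
  pipeline_config(mode = "synthetic", out_dir = out_dir, synth = synth,
                  n_hvg = 50, n_pcs = 10, k_neighbors = 10,
                  resolution = 0.8, n_permutations = 200, seed = seed)
}
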