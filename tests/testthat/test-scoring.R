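# Module scores, fold-change ranking with randomized ties, and the
# preranked GSEA running-sum statistic.

test_that("a control pool equal to the signature scores zero everywhere", {
  withr::local_seed(1)
  nm <- toy_normalized(matrix(rnorm(50, 2), 10, 5))
  sig <- gene_signature("self", c("g1", "g3"))
  sc <- module_score(nm, sig, ctrl_genes = c("g1", "g3"))
  expect_true(all(abs(sc$score) < 1e-12))
})

test_that("module score equals the hand-computed difference of means", {
  vals <- rbind(c(1, 2, 6), c(0, 4, 5))
  nm <- toy_normalized(vals)
  sig <- gene_signature("s", "g3")
  sc <- module_score(nm, sig, n_bins = 1, n_ctrl = 100, seed = 1)
  # one bin: controls are all non-signature genes
  expect_equal(sc$score, c(6 - 1.5, 5 - 2))
  expect_setequal(attr(sc, "control_genes"), c("g1", "g2"))
})

test_that("module scores are reproducible from the seed and drop absent genes", {
  withr::local_seed(2)
  nm <- toy_normalized(matrix(rnorm(600), 20, 30))
  sig <- gene_signature("s", c("g2", "g9", "NotThere"))
  a <- module_score(nm, sig, n_bins = 5, n_ctrl = 3, seed = 7)
  b <- module_score(nm, sig, n_bins = 5, n_ctrl = 3, seed = 7)
  expect_identical(a$score, b$score)
  sig_none <- gene_signature("ghost", "NotThere")
  expect_error(module_score(nm, sig_none), "ghost")
})

test_that("module scores are invariant to gene order and global shifts", {
  withr::local_seed(3)
  vals <- matrix(rnorm(200, 3), 10, 20)
  nm <- toy_normalized(vals)
  sig <- gene_signature("s", c("g4", "g11"))
  perm <- sample(20)
  nm_p <- toy_normalized(vals[, perm], genes = nm$genes[perm])
  a <- module_score(nm, sig, n_bins = 4, n_ctrl = 5, seed = 1)
  b <- module_score(nm_p, sig, n_bins = 4, n_ctrl = 5, seed = 1)
  expect_equal(sort(attr(a, "control_genes")), sort(attr(b, "control_genes")))
  # shifting every gene in every cell by a constant leaves scores unchanged
  nm_shift <- toy_normalized(vals + 5, genes = nm$genes)
  c_ <- module_score(nm_shift, sig, ctrl_genes = attr(a, "control_genes"))
  a_fixed <- module_score(nm, sig, ctrl_genes = attr(a, "control_genes"))
  expect_equal(c_$score, a_fixed$score, tolerance = 1e-10)
})

test_that("fold changes follow the de-logged pseudocount formula", {
  nm <- toy_normalized(rbind(log(4), log(2)), genes = "g1",
                       barcodes = c("a", "b"))
  rl <- fold_change(nm, "a", "b")
  expect_equal(rl$stat, log2((3 + 1) / (1 + 1))) # de-logged means 3 and 1
  nm2 <- toy_normalized(matrix(rnorm(40), 4, 10))
  ra <- fold_change(nm2, c(1, 2), c(3, 4))
  rb <- fold_change(nm2, c(3, 4), c(1, 2))
  expect_equal(ra$stat[match(nm2$genes, ra$gene)],
               -rb$stat[match(nm2$genes, rb$gene)])
  expect_error(fold_change(nm2, c(1, 2), c(2, 3)), "disjoint")
  expect_error(fold_change(nm2, integer(0), 1:2), "non-empty")
})

test_that("identical groups give all-zero statistics", {
  withr::local_seed(4)
  vals <- matrix(rnorm(60), 6, 10)
  nm <- toy_normalized(rbind(vals[1:3, ], vals[1:3, ]),
                       barcodes = paste0("c", 1:6))
  rl <- fold_change(nm, paste0("c", 1:3), paste0("c", 4:6))
  expect_true(all(rl$stat == 0))
})

test_that("tied statistics are permuted by the tie seed, same multiset", {
  nm <- toy_normalized(matrix(1, 3, 30))
  r1 <- fold_change(nm, 1, 2:3, tie_seed = 1)
  r2 <- fold_change(nm, 1, 2:3, tie_seed = 2)
  expect_false(identical(r1$gene, r2$gene))
  expect_setequal(r1$gene, r2$gene)
  expect_identical(fold_change(nm, 1, 2:3, tie_seed = 1)$gene, r1$gene)
})

make_ranked <- function(stat, genes = sprintf("g%02d", seq_along(stat))) {
  ord <- order(-stat)
  structure(data.frame(gene = genes[ord], stat = stat[ord],
                       stringsAsFactors = FALSE),
            class = c("RankedList", "data.frame"))
}

test_that("GSEA extremes: top-gene signature gives ES 1, bottom gives -1", {
  rl <- make_ranked(c(3, 2, 1, 0.5))
  top <- gsea_preranked(rl, gene_signature("t", rl$gene[1]),
                        n_permutations = 10, seed = 1)
  expect_equal(top$es, 1)
  rl2 <- make_ranked(c(3, 2, -1, -2))
  bottom <- gsea_preranked(rl2, gene_signature("b", rl2$gene[4]),
                           n_permutations = 10, seed = 1)
  expect_equal(bottom$es, -1)
})

test_that("ES is invariant to positive rescaling of the statistics", {
  withr::local_seed(5)
  stat <- rnorm(30)
  sig <- gene_signature("s", sprintf("g%02d", sample(30, 6)))
  e1 <- gsea_preranked(make_ranked(stat), sig, n_permutations = 10, seed = 1)$es
  e2 <- gsea_preranked(make_ranked(stat * 7.5), sig,
                       n_permutations = 10, seed = 1)$es
  expect_equal(e1, e2)
})

test_that("ES equals the brute-force running sum on short lists", {
  withr::local_seed(6)
  for (i in 1:50) {
    n <- sample(3:20, 1)
    stat <- round(rnorm(n), 2)
    size <- sample(seq_len(n - 1), 1)
    genes <- sprintf("g%02d", 1:n)
    sig <- gene_signature("s", sample(genes, size))
    rl <- make_ranked(stat, genes)
    es <- gsea_preranked(rl, sig, n_permutations = 5, seed = 1)$es
    expect_equal(es, oracle_es(rl$stat, rl$gene %in% sig$genes))
  }
})

test_that("ES agrees with the independent fgsea implementation", {
  withr::local_seed(7)
  for (i in 1:10) {
    stat <- sort(rnorm(100), decreasing = TRUE)
    genes <- sprintf("g%03d", 1:100)
    sel <- sort(sample(100, 15))
    rl <- make_ranked(stat, genes)
    es <- gsea_preranked(rl, gene_signature("s", genes[sel]),
                         n_permutations = 5, seed = 1)$es
    expect_equal(es, fgsea::calcGseaStat(stat, sel, gseaParam = 1),
                 tolerance = 1e-12)
  }
})

test_that("GSEA degenerate signatures error and p respects its floor", {
  rl <- make_ranked(c(2, 1, -1))
  expect_error(gsea_preranked(rl, gene_signature("all", rl$gene),
                              n_permutations = 10, seed = 1),
               "covers the whole")
  expect_error(gsea_preranked(rl, gene_signature("none", "zzz"),
                              n_permutations = 10, seed = 1),
               "no genes")
  res <- gsea_preranked(rl, gene_signature("one", rl$gene[1]),
                        n_permutations = 10, seed = 1)
  expect_gte(res$pval, 1 / 11)
  expect_lte(abs(res$es), 1)
})

test_that("the planted program is detected with positive ES and small p", {
  cfg <- synth_config(n_samples = 2, cells_per_sample = 500,
                      doublet_rate = 0, low_count_rate = 0, seed = 1)
  sim <- simulate_hto(cfg)
  expr <- simulate_expression(cfg, sim$truth)
  nm <- log_normalize(expr)
  rl <- fold_change(nm, nm$barcodes[sim$truth$condition == "treg_depleted"],
                    nm$barcodes[sim$truth$condition == "control"])
  res <- gsea_preranked(rl, gene_signature("program", cfg$program_spec$genes),
                        n_permutations = 500, seed = 1)
  expect_gt(res$es, 0)
  expect_lt(res$pval, 0.05)
})
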