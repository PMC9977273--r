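#!/usr/bin/env Rscript
# Signature scoring and enrichment: expression-bin-matched module score
# of the planted program per cluster, log2 fold-change ranking between
# conditions (ties in random order), and preranked GSEA of the program.

suppressMessages(library(scvalley))

m <- read_10x_mtx("results/data")
truth <- read.delim("results/data/truth.tsv")
clusters <- read.delim("results/analysis/clusters.tsv")

m <- subset_cells(m, clusters$barcode)
mq <- filter_genes(m, min_cells = 3)$matrix
nm <- log_normalize(mq)

program <- gene_signature("planted_program", synth_config()$program_spec$genes)
scores <- module_score(nm, program, n_bins = 24, n_ctrl = 100, seed = 1)
by_cluster <- tapply(scores$score, clusters$cluster, mean)
cat("mean program module score per cluster:\n")
print(round(by_cluster, 3))

rl <- fold_change(nm, clusters$barcode[clusters$condition == "treg_depleted"],
                  clusters$barcode[clusters$condition == "control"],
                  tie_seed = 1)
res <- gsea_preranked(rl, program, n_permutations = 1000, seed = 1)
print(res)

write_table(data.frame(signature = program$name, es = res$es, nes = res$nes,
                       pval = res$pval, size = res$size),
            "results/analysis/gsea.tsv")
write_table(cbind(scores, cluster = clusters$cluster),
            "results/analysis/module_scores.tsv")
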