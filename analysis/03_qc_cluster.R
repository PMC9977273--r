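#!/usr/bin/env Rscript
# QC and clustering of the demultiplexed singlets: cell filter (>=200
# transcripts, <=15% mitochondrial), gene-family exclusions, log
# normalization (1e4), 2000 variable genes, scaling, 50 PCs, SNN graph,
# Louvain at resolution 0.8. Checks whether the planted rare cluster
# comes out as its own condition-restricted community.

suppressMessages(library(scvalley))

m <- read_10x_mtx("results/data")
truth <- read.delim("results/data/truth.tsv")
calls <- read.delim("results/analysis/demux_calls.tsv")

m <- subset_cells(m, calls$barcode[calls$call == "singlet"])
cellf <- filter_cells(m, min_transcripts = 200, max_mito = 0.15)
genef <- filter_genes(cellf$matrix, min_cells = 3)
mq <- genef$matrix
cat("QC:", n_cells(m), "singlets ->", n_cells(mq), "cells;",
    sum(m$features$type == "Gene Expression"), "->",
    sum(mq$features$type == "Gene Expression"), "genes\n")

nm <- log_normalize(mq, scale_factor = 1e4)
hvg <- select_variable_genes(nm, min(2000, length(nm$genes)))
emb <- pca_embed(scale_and_regress(nm, hvg), 50)
labels <- louvain_cluster(snn_graph(emb, k_neighbors = 20), resolution = 0.8,
                          seed = 1)

tr <- truth[match(nm$barcodes, truth$barcode), ]
out <- data.frame(barcode = nm$barcodes, cluster = as.integer(labels),
                  condition = tr$condition, truth_cluster = tr$cluster)
write_table(out, "results/analysis/clusters.tsv")

cat("clusters found:", length(unique(labels)), "\n")
print(table(cluster = out$cluster, truth = out$truth_cluster))
kilr_frac <- tapply(tr$cluster == "kilr", labels, mean)
rare <- names(which.max(kilr_frac))
cat(sprintf("rare cluster -> label %s (%.0f%% kilr); condition purity %.1f%%\n",
            rare, 100 * max(kilr_frac),
            100 * mean(tr$condition[labels == as.integer(rare)] ==
                         "treg_depleted")))
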