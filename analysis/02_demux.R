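#!/usr/bin/env Rscript
# Demultiplex the simulated droplets: per-hashtag histograms, 5-point
# sliding-window smoothing, gradient-descent read limits, assignment with
# doublet exclusion. Compares the calls against the ground truth.

suppressMessages(library(scvalley))

m <- read_10x_mtx("results/data")
truth <- read.delim("results/data/truth.tsv")

res <- demux_hashtags(m, window = 5, min_transcripts = 200)
print(res)

dir.create("results/analysis", showWarnings = FALSE, recursive = TRUE)
write_table(res$calls, "results/analysis/demux_calls.tsv")
write_table(data.frame(hashtag = names(res$limits),
                       limit = as.integer(res$limits)),
            "results/analysis/demux_limits.tsv")

stopifnot(identical(res$calls$barcode, truth$barcode))
singl <- !truth$doublet
acc <- mean(res$calls$call[singl] == "singlet" &
              res$calls$sample[singl] == truth$sample1[singl])
rec <- mean(res$calls$call[truth$doublet] == "doublet")
cat(sprintf("singlet label accuracy: %.4f\ndoublet exclusion recall: %.4f\n",
            acc, rec))
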