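# scvalley

Demultiplexing of cell-hashing (hashtag oligo) droplet data by histogram
valley detection, with the downstream single-cell RNA-seq stages needed
to take the demultiplexed cells through QC, clustering, signature
scoring and gene-set enrichment — plus a droplet simulator with known
ground truth so the whole chain is testable end to end.

## Who this is for

Groups running multiplexed single-cell experiments (several
hashtag-labelled samples pooled into one 10x run) who want a simple,
auditable, distribution-free threshold rule for sample assignment
instead of a fitted mixture model, and a reproducible reference
implementation of the standard analysis that follows.

## The core algorithm

For each hashtag *h*, over all cells with ≥ 200 transcripts, build the
histogram *n(c)* of cells having exactly *c* reads of *h*. A working
hashtag is bimodal: an ambient mode near zero and a signal mode at the
staining level. Then:

1. smooth *n(c)* with a centered 5-point sliding window;
2. ascend from bin 0 to the first local maximum, then descend along the
   gradient — move right while the next smoothed value is strictly
   lower. The stopping bin is the read limit *L<sub>h</sub>*;
3. associate a cell with *h* iff its raw count ≥ *L<sub>h</sub>*.
   Exactly one association → singlet; two or more → doublet (excluded);
   none → unassigned.

Downstream: strict QC thresholds (total < 200 or mito fraction > 0.15
drop a cell; mito/ribo/TCR-V(D)J gene families and genes detected in
< 3 cells are excluded), log normalization (scale factor 10⁴),
trend-standardized variable-gene selection, covariate-regressed scaling,
exact PCA, Jaccard-weighted SNN graph, resolution-parameterised Louvain
clustering, expression-bin-matched module scores, and preranked GSEA
(log2 fold-change ranking with randomized ties; weighted running-sum ES
with a gene-sampling permutation null).

## Worked example

Simulate a 3-sample experiment, write it as a 10x-style triplet, read it
back and demultiplex:

```r
library(scvalley)

cfg <- synth_config(n_samples = 3, cells_per_sample = 500, seed = 42)
sim <- simulate_experiment(cfg, "demo")
m <- read_10x_mtx("demo")
m
#> CountMatrix: 1500 cells x 2003 features (Antibody Capture: 3, Gene Expression: 2000)

res <- demux_hashtags(m, window = 5, min_transcripts = 200)
res
#> DemuxResult: singlet=1310, doublet=164, unassigned=1, removed_low_count=25
#> limits: HTO1:12, HTO2:10, HTO3:10
```

The per-hashtag limits (12, 10, 10) are the detected valley positions of
the smoothed histograms; 25 droplets failed the 200-transcript
pre-filter and 164 were excluded as multi-hashtag doublets. Against the
simulator's ground truth this call set recovers 98.2% of true singlet
labels and excludes 98.8% of true doublets:

```r
truth <- sim$truth
singl <- !truth$doublet
mean(res$calls$call[singl] == "singlet" &
     res$calls$sample[singl] == truth$sample1[singl])
#> [1] 0.982
mean(res$calls$call[truth$doublet] == "doublet")
#> [1] 0.988
```

`run_pipeline(pipeline_config(mode = "synthetic", out_dir = "out"))`
runs the whole chain (demux → QC → normalize → variable genes → PCA →
SNN → Louvain → scores → GSEA) and writes per-stage TSVs plus a JSON
manifest. The `analysis/` directory holds the same workflow as numbered
narrative scripts (`01_simulate.R` … `04_scoring_gsea.R`) writing under
`results/`.

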