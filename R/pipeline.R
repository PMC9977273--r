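# End-to-end orchestration: pre-filter -> demux -> QC -> normalize ->
# variable genes -> scale/regress -> PCA -> SNN -> Louvain -> module
# scores -> fold changes -> GSEA, with per-stage artifacts and a JSON
# manifest. Two presets mirror the two analysis passes of the reference
# workflow: "first_pass" (2000 variable genes, 50 PCs, resolution 0.8)
# and "reanalysis" (800, 12, 0.3).

#' Pipeline configuration
#'
#' @param mode `"synthetic"` (simulate the input) or `"tenx"` (read an
#'   existing 10x triplet directory).
#' @param out_dir directory for all artifacts.
#' @param input_dir 10x triplet directory (`tenx` mode).
#' @param synth a [synth_config()] (`synthetic` mode).
#' @param sample_conditions named vector mapping hashtag id to condition
#'   label; derived from the simulator in synthetic mode.
#' @param preset `"first_pass"` or `"reanalysis"`; fills `n_hvg`,
#'   `n_pcs`, `resolution` unless they are given explicitly.
#' @param window,min_transcripts demultiplexer parameters.
#' @param max_mito,min_cells,exclusion_patterns QC parameters.
#' @param scale_factor,n_hvg,clip,n_pcs,k_neighbors,prune,resolution
#'   normalization / clustering parameters.
#' @param n_bins,n_ctrl module-score parameters.
#' @param n_permutations,weight_exponent GSEA parameters.
#' @param gmt_path optional GMT file of signatures to score; in
#'   synthetic mode the planted program is always scored as well.
#' @param seed master seed for every stochastic stage.
#' @return a validated `PipelineConfig` list.
#' @export
pipeline_config <- function(mode = c("synthetic", "tenx"), out_dir,
                            input_dir = NULL, synth = synth_config(),
                            sample_conditions = NULL,
                            preset = c("first_pass", "reanalysis"),
                            window = 5, min_transcripts = 200,
                            max_mito = 0.15, min_cells = 3,
                            exclusion_patterns = default_exclusion_patterns(),
                            scale_factor = 1e4, n_hvg = NULL, clip = 10,
                            n_pcs = NULL, k_neighbors = 20, prune = 1/15,
                            resolution = NULL, n_bins = 24, n_ctrl = 100,
                            n_permutations = 1000, weight_exponent = 1,
                            gmt_path = NULL, seed = 1) {
  mode <- match.arg(mode)
  preset <- match.arg(preset)
  defaults <- list(first_pass = list(n_hvg = 2000, n_pcs = 50, resolution = 0.8),
                   reanalysis = list(n_hvg = 800, n_pcs = 12, resolution = 0.3))[[preset]]
  cfg <- list(mode = mode, out_dir = out_dir, input_dir = input_dir,
              synth = synth, sample_conditions = sample_conditions,
              preset = preset, window = window,
              min_transcripts = min_transcripts, max_mito = max_mito,
              min_cells = min_cells, exclusion_patterns = exclusion_patterns,
              scale_factor = scale_factor,
              n_hvg = if (is.null(n_hvg)) defaults$n_hvg else n_hvg,
              clip = clip,
              n_pcs = if (is.null(n_pcs)) defaults$n_pcs else n_pcs,
              k_neighbors = k_neighbors, prune = prune,
              resolution = if (is.null(resolution)) defaults$resolution else resolution,
              n_bins = n_bins, n_ctrl = n_ctrl,
              n_permutations = n_permutations,
              weight_exponent = weight_exponent,
              gmt_path = gmt_path, seed = as.integer(seed))
  class(cfg) <- "PipelineConfig"
  validate_pipeline_config(cfg)
}

#' @rdname pipeline_config
#' @param cfg a `PipelineConfig`.
#' @export
validate_pipeline_config <- function(cfg) {
  stopifnot(cfg$window >= 1, cfg$window %% 2 == 1,
            cfg$min_transcripts >= 0, cfg$max_mito >= 0, cfg$max_mito <= 1,
            cfg$min_cells >= 0, cfg$scale_factor > 0, cfg$n_hvg >= 1,
            cfg$n_pcs >= 1, cfg$k_neighbors >= 1, cfg$resolution > 0,
            cfg$n_bins >= 1, cfg$n_ctrl >= 1, cfg$n_permutations >= 1)
  if (cfg$mode == "tenx" && is.null(cfg$input_dir))
    stop("tenx mode requires input_dir", call. = FALSE)
  if (cfg$mode == "synthetic") validate_synth_config(cfg$synth)
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys are the arguments of [pipeline_config()]; a `synth`
#' block holds [synth_config()] arguments.
#'
#' @param path YAML file.
#' @param out_dir overrides the file's `out_dir` when given.
#' @return a `PipelineConfig`.
#' @export
read_pipeline_config <- function(path, out_dir = NULL) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$synth)) raw$synth <- do.call(synth_config, raw$synth)
  if (!is.null(raw$sample_conditions))
    raw$sample_conditions <- unlist(raw$sample_conditions)
  if (!is.null(out_dir)) raw$out_dir <- out_dir
  do.call(pipeline_config, raw)
}

.stage_log <- function(verbose, ...) if (verbose) message(sprintf(...))

#' Run the full pipeline
#'
#' Executes demultiplexing, QC, clustering, scoring and GSEA in the
#' fixed order, writing per-stage TSV artifacts and a JSON manifest
#' (parameters, seeds, per-stage shapes) into `cfg$out_dir`. Rerunning
#' with the same configuration reproduces identical outputs.
#'
#' @param cfg a [pipeline_config()].
#' @param verbose log stage tallies via `message()`.
#' @return the manifest list, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(cfg, verbose = TRUE) {
  validate_pipeline_config(cfg)
  out_dir <- cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- list()
  note <- function(name, ...) stages[[name]] <<- list(...)

  # --- input ---------------------------------------------------------
  truth <- NULL
  if (cfg$mode == "synthetic") {
    sim <- simulate_experiment(cfg$synth, file.path(out_dir, "input"))
    truth <- sim$truth
    input_dir <- sim$dir
    hashtags <- sprintf("HTO%d", seq_len(cfg$synth$n_samples))
    sample_conditions <- .sample_condition(seq_len(cfg$synth$n_samples),
                                           cfg$synth$n_samples)
    names(sample_conditions) <- hashtags
  } else {
    input_dir <- cfg$input_dir
    sample_conditions <- cfg$sample_conditions
  }
  m <- read_10x_mtx(input_dir)
  note("input", n_cells = n_cells(m), n_features = n_features(m))
  .stage_log(verbose, "input: %d droplets x %d features", n_cells(m), n_features(m))

  # --- demultiplexing ------------------------------------------------
  demux <- demux_hashtags(m, window = cfg$window,
                          min_transcripts = cfg$min_transcripts)
  write_table(demux$calls, file.path(out_dir, "demux_calls.tsv"))
  write_table(data.frame(hashtag = names(demux$limits),
                         limit = as.integer(demux$limits)),
              file.path(out_dir, "demux_limits.tsv"))
  note("demux", n_cells = n_cells(m), tallies = as.list(demux$tallies),
       limits = as.list(demux$limits))
  .stage_log(verbose, "demux: %s",
             paste(sprintf("%s=%d", names(demux$tallies), demux$tallies),
                   collapse = ", "))

  singlets <- demux$calls$barcode[demux$calls$call == "singlet"]
  m <- subset_cells(m, singlets)
  cell_sample <- demux$calls$sample[match(m$barcodes, demux$calls$barcode)]
  condition <- if (!is.null(sample_conditions))
    unname(sample_conditions[cell_sample]) else rep(NA_character_, n_cells(m))
  m$condition <- condition

  # --- QC: cell filter first, then gene exclusions -------------------
  metrics <- compute_cell_metrics(m)
  cellf <- filter_cells(m, metrics, min_transcripts = cfg$min_transcripts,
                        max_mito = cfg$max_mito)
  genef <- filter_genes(cellf$matrix,
                        exclusion_patterns = cfg$exclusion_patterns,
                        min_cells = cfg$min_cells)
  mq <- genef$matrix
  write_table(metrics$cell_metrics, file.path(out_dir, "qc_cells.tsv"))
  note("qc", cells_in = n_cells(m), cells_out = n_cells(mq),
       genes_in = sum(m$features$type == "Gene Expression"),
       genes_out = sum(mq$features$type == "Gene Expression"),
       cell_tallies = as.list(cellf$tallies),
       gene_tallies = as.list(genef$tallies))
  .stage_log(verbose, "qc: %d -> %d cells, %d -> %d genes",
             n_cells(m), n_cells(mq),
             sum(m$features$type == "Gene Expression"),
             sum(mq$features$type == "Gene Expression"))

  # --- normalize / reduce / cluster ----------------------------------
  nm <- log_normalize(mq, scale_factor = cfg$scale_factor)
  hvg <- select_variable_genes(nm, min(cfg$n_hvg, length(nm$genes)))
  scaled <- scale_and_regress(nm, hvg, clip = cfg$clip)
  emb <- pca_embed(scaled, min(cfg$n_pcs, ncol(scaled), nrow(scaled)))
  graph <- snn_graph(emb, k_neighbors = cfg$k_neighbors, prune = cfg$prune)
  labels <- louvain_cluster(graph, resolution = cfg$resolution, seed = cfg$seed)
  label_df <- data.frame(barcode = nm$barcodes, cluster = as.integer(labels),
                         sample = cell_sample[match(nm$barcodes, m$barcodes)],
                         condition = nm$condition, stringsAsFactors = FALSE)
  write_table(label_df, file.path(out_dir, "clusters.tsv"))
  note("cluster", n_cells = nrow(label_df), n_hvg = length(hvg),
       n_pcs = ncol(emb), n_clusters = length(unique(labels)))
  .stage_log(verbose, "cluster: %d cells, %d clusters (resolution %.2f)",
             nrow(label_df), length(unique(labels)), cfg$resolution)

  # --- signatures: module scores, fold change, GSEA ------------------
  sigs <- list()
  if (cfg$mode == "synthetic")
    sigs$planted_program <- gene_signature("planted_program",
                                           cfg$synth$program_spec$genes)
  if (!is.null(cfg$gmt_path)) sigs <- c(sigs, read_gmt(cfg$gmt_path))

  score_rows <- list()
  gsea_rows <- list()
  conds <- unique(stats::na.omit(nm$condition))
  rl <- NULL
  if (length(conds) >= 2) {
    rl <- fold_change(nm, nm$barcodes[nm$condition == "treg_depleted"],
                      nm$barcodes[nm$condition == "control"],
                      tie_seed = cfg$seed)
    write_table(as.data.frame(rl), file.path(out_dir, "ranked_genes.tsv"))
  }
  for (sig in sigs) {
    detected <- intersect(sig$genes, nm$genes)
    if (length(detected) == 0) {
      warning("signature '", sig$name, "' has no detected genes; skipped")
      next
    }
    sc <- module_score(nm, sig, n_bins = cfg$n_bins, n_ctrl = cfg$n_ctrl,
                       seed = cfg$seed)
    score_rows[[sig$name]] <- data.frame(signature = sig$name, sc,
                                         stringsAsFactors = FALSE)
    if (!is.null(rl) && length(detected) < length(nm$genes)) {
      gr <- gsea_preranked(rl, sig, weight_exponent = cfg$weight_exponent,
                           n_permutations = cfg$n_permutations, seed = cfg$seed)
      gsea_rows[[sig$name]] <- data.frame(signature = sig$name, es = gr$es,
                                          nes = gr$nes, pval = gr$pval,
                                          size = gr$size,
                                          stringsAsFactors = FALSE)
      .stage_log(verbose, "gsea '%s': ES %.3f, p %.4g", sig$name, gr$es, gr$pval)
    }
  }
  if (length(score_rows))
    write_table(do.call(rbind, score_rows), file.path(out_dir, "module_scores.tsv"))
  if (length(gsea_rows))
    write_table(do.call(rbind, gsea_rows), file.path(out_dir, "gsea.tsv"))
  note("scoring", n_signatures = length(sigs),
       n_gsea = length(gsea_rows))

  manifest <- list(
    pipeline = "scvalley",
    version = as.character(utils::packageVersion("scvalley")),
    mode = cfg$mode, preset = cfg$preset, seed = cfg$seed,
    parameters = cfg[c("window", "min_transcripts", "max_mito", "min_cells",
                       "scale_factor", "n_hvg", "clip", "n_pcs",
                       "k_neighbors", "prune", "resolution", "n_bins",
                       "n_ctrl", "n_permutations", "weight_exponent")],
    artifacts = c("demux_calls.tsv", "demux_limits.tsv", "qc_cells.tsv",
                  "clusters.tsv",
                  if (length(score_rows)) "module_scores.tsv",
                  if (length(gsea_rows)) "gsea.tsv"),
    stages = stages
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
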