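# Droplet simulator with known ground truth. Emulates the study design the
# pipeline targets: 6 hashtagged samples (~1000 cells each), two conditions
# (Treg-depleted vs control), ambient vs own-hashtag signal, cross-sample
# doublets, a rare cluster planted almost exclusively in one condition, and
# an IL-2-responsive-like gene program shifted between conditions.

.CONDITIONS <- c("treg_depleted", "control")

.derive_seed <- function(seed, k) as.integer((as.numeric(seed) + k) %% 2147483647)

#' Gene universe for the simulator
#'
#' Generic gene names plus small named blocks of mitochondrial (`mt-`),
#' ribosomal (`Rps`/`Rpl`) and TCR V(D)J (`Trav`/`Trbv`/...) genes at the
#' end of the universe so the QC exclusion rules have real targets.
#'
#' @param n_genes total number of genes (>= 100).
#' @return character vector of gene names.
#' @export
gene_universe <- function(n_genes) {
  stopifnot(n_genes >= 100)
  genes <- sprintf("Gene%04d", seq_len(n_genes))
  special <- c("mt-Nd1", "mt-Nd2", "mt-Co1", "mt-Co2", "mt-Co3",
               "mt-Cytb", "mt-Atp6", "mt-Atp8", "mt-Nd4", "mt-Nd5",
               paste0("Rps", 1:6), paste0("Rpl", 1:6),
               paste0("Trav", 1:3), paste0("Trbv", 1:3), "Traj1", "Trbj1")
  genes[(n_genes - length(special) + 1):n_genes] <- special
  genes
}

.default_cluster_spec <- function() {
  list(
    effector = list(freq = c(treg_depleted = 0.60, control = 0.68),
                    markers = sprintf("Gene%04d", 1:20), log2fc = 2),
    memory = list(freq = c(treg_depleted = 0.30, control = 0.32),
                  markers = sprintf("Gene%04d", 21:40), log2fc = 2),
    kilr = list(freq = c(treg_depleted = 0.10, control = 0.00),
                markers = sprintf("Gene%04d", 41:65), log2fc = 3)
  )
}

.default_program_spec <- function() {
  list(genes = sprintf("Gene%04d", 101:140),
       effect = c(treg_depleted = 1, control = 0))
}

#' Simulation configuration
#'
#' Defaults mirror the targeted experiment: 6 hashtag-labelled samples
#' aiming at 1000 cells each, overdispersed (negative binomial) hashtag
#' counts with ambient mean 2 vs own-hashtag mean 50 (valley of the
#' pooled histogram in the 10-40 count range), 10% cross-sample doublets,
#' three transcriptional clusters of which one ("kilr") is planted almost
#' exclusively in the Treg-depleted condition, and a 40-gene program
#' up-shifted by 1 log2 unit in that condition.
#'
#' @param n_samples number of hashtagged samples.
#' @param cells_per_sample droplets per sample (droplet total is
#'   `n_samples * cells_per_sample`).
#' @param doublet_rate fraction of droplets carrying two samples, in `[0,1)`.
#' @param ambient_mean expected ambient reads of a non-own hashtag per cell.
#' @param signal_mean expected reads of the own hashtag (must exceed
#'   `ambient_mean`).
#' @param dispersion negative binomial size parameter (> 0).
#' @param n_genes size of the gene universe.
#' @param mean_library_size expected transcripts per normal droplet.
#' @param library_sd_log sdlog of the log-normal library-size distribution.
#' @param low_count_rate fraction of degraded droplets with totals below the
#'   200-transcript pre-filter.
#' @param cluster_spec named list; each entry has `freq` (per-condition
#'   frequencies, each condition's frequencies summing to 1 over clusters),
#'   `markers` (gene names) and `log2fc`.
#' @param program_spec list with `genes` and per-condition `effect` (log2).
#' @param mito_fraction_range range the per-cell mitochondrial fraction is
#'   drawn from, inside `[0,1]`.
#' @param seed integer seed; all draws derive from it.
#' @return a validated `SynthConfig` list.
#' @export
synth_config <- function(n_samples = 6, cells_per_sample = 1000,
                         doublet_rate = 0.1, ambient_mean = 2,
                         signal_mean = 50, dispersion = 10,
                         n_genes = 2000, mean_library_size = 5000,
                         library_sd_log = 0.3, low_count_rate = 0.01,
                         cluster_spec = .default_cluster_spec(),
                         program_spec = .default_program_spec(),
                         mito_fraction_range = c(0.02, 0.08), seed = 1) {
  cfg <- list(n_samples = n_samples, cells_per_sample = cells_per_sample,
              doublet_rate = doublet_rate, ambient_mean = ambient_mean,
              signal_mean = signal_mean, dispersion = dispersion,
              n_genes = n_genes, mean_library_size = mean_library_size,
              library_sd_log = library_sd_log, low_count_rate = low_count_rate,
              cluster_spec = cluster_spec, program_spec = program_spec,
              mito_fraction_range = mito_fraction_range, seed = as.integer(seed))
  class(cfg) <- "SynthConfig"
  validate_synth_config(cfg)
}

#' @rdname synth_config
#' @param cfg a `SynthConfig`.
#' @export
validate_synth_config <- function(cfg) {
  stopifnot(cfg$n_samples >= 2, cfg$cells_per_sample >= 1,
            cfg$doublet_rate >= 0, cfg$doublet_rate < 1,
            cfg$ambient_mean >= 0, cfg$dispersion > 0,
            is.finite(cfg$signal_mean), is.finite(cfg$ambient_mean))
  if (cfg$signal_mean <= cfg$ambient_mean)
    stop("config error: signal_mean must exceed ambient_mean ",
         "(no detectable valley otherwise)", call. = FALSE)
  if (any(cfg$mito_fraction_range < 0) || any(cfg$mito_fraction_range > 1) ||
      diff(cfg$mito_fraction_range) < 0)
    stop("config error: mito_fraction_range must be an interval in [0,1]",
         call. = FALSE)
  for (cond in .CONDITIONS) {
    tot <- sum(vapply(cfg$cluster_spec, function(cl) cl$freq[[cond]], 0))
    if (abs(tot - 1) > 1e-8)
      stop("config error: cluster frequencies for condition '", cond,
           "' sum to ", tot, ", not 1", call. = FALSE)
  }
  cfg
}

.sample_condition <- function(sample_idx, n_samples) {
  # first half of the samples are the Treg-depleted mice
  ifelse(sample_idx <= n_samples / 2, "treg_depleted", "control")
}

#' Simulate hashtag (antibody-capture) counts with ground truth
#'
#' Each singlet's own hashtag is negative binomial with mean
#' `signal_mean`; every other hashtag is negative binomial with mean
#' `ambient_mean`. Doublets receive signal on two distinct hashtags chosen
#' uniformly. The ground truth also fixes each droplet's condition and
#' planted cluster so expression can be simulated on top.
#'
#' @param cfg a [synth_config()].
#' @return list with `matrix` (a `CountMatrix` of antibody-capture
#'   features) and `truth` (data.frame: `barcode`, `sample1`, `sample2`,
#'   `doublet`, `condition`, `cluster`, `low_count`).
#' @export
simulate_hto <- function(cfg) {
  validate_synth_config(cfg)
  n <- cfg$n_samples * cfg$cells_per_sample
  hashtags <- sprintf("HTO%d", seq_len(cfg$n_samples))
  cl_names <- names(cfg$cluster_spec)

  withr::with_seed(.derive_seed(cfg$seed, 0), {
    doublet <- stats::runif(n) < cfg$doublet_rate
    s1 <- sample.int(cfg$n_samples, n, replace = TRUE)
    # uniform among the other samples
    s2 <- ((s1 - 1 + sample.int(cfg$n_samples - 1L, n, replace = TRUE)) %%
             cfg$n_samples) + 1L
    s2[!doublet] <- NA_integer_
    condition <- .sample_condition(s1, cfg$n_samples)
    cluster <- vapply(condition, function(cond) {
      p <- vapply(cfg$cluster_spec, function(cl) cl$freq[[cond]], 0)
      sample(cl_names, 1, prob = p)
    }, "")
    low_count <- stats::runif(n) < cfg$low_count_rate

    counts <- matrix(stats::rnbinom(n * cfg$n_samples, mu = cfg$ambient_mean,
                                    size = cfg$dispersion),
                     nrow = n, ncol = cfg$n_samples)
    counts[cbind(seq_len(n), s1)] <-
      stats::rnbinom(n, mu = cfg$signal_mean, size = cfg$dispersion)
    if (any(doublet))
      counts[cbind(which(doublet), s2[doublet])] <-
        stats::rnbinom(sum(doublet), mu = cfg$signal_mean, size = cfg$dispersion)
  })

  barcodes <- sprintf("BC%06d", seq_len(n))
  truth <- data.frame(
    barcode = barcodes,
    sample1 = hashtags[s1],
    sample2 = ifelse(is.na(s2), NA_character_, hashtags[s2]),
    doublet = doublet,
    condition = condition,
    cluster = cluster,
    low_count = low_count,
    stringsAsFactors = FALSE
  )
  features <- data.frame(id = hashtags, name = hashtags,
                         type = "Antibody Capture", stringsAsFactors = FALSE)
  list(matrix = count_matrix(counts, barcodes, features, condition = condition),
       truth = truth)
}

#' Simulate gene-expression counts on top of a hashtag ground truth
#'
#' Gamma-Poisson (negative binomial) counts with log-normal library sizes;
#' cluster markers and the condition program shift gene means by their
#' configured log2 effects; a designated mitochondrial gene block receives
#' a per-cell fraction drawn uniformly from `mito_fraction_range`;
#' droplets flagged `low_count` get totals below the 200-transcript
#' pre-filter.
#'
#' @param cfg a [synth_config()].
#' @param truth the truth data.frame from [simulate_hto()].
#' @return a `CountMatrix` of gene-expression features.
#' @export
simulate_expression <- function(cfg, truth) {
  validate_synth_config(cfg)
  genes <- gene_universe(cfg$n_genes)
  all_markers <- unlist(lapply(cfg$cluster_spec, `[[`, "markers"), use.names = FALSE)
  missing <- setdiff(c(all_markers, cfg$program_spec$genes), genes)
  if (length(missing))
    stop("config error: marker/program gene(s) outside gene universe: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)

  n <- nrow(truth)
  mito <- grepl("^mt-", genes)

  withr::with_seed(.derive_seed(cfg$seed, 1), {
    base <- stats::rlnorm(cfg$n_genes, meanlog = 0, sdlog = 1)
    totals <- stats::rlnorm(n, meanlog = log(cfg$mean_library_size),
                            sdlog = cfg$library_sd_log)
    totals[truth$low_count] <- stats::runif(sum(truth$low_count), 50, 150)
    mito_frac <- stats::runif(n, cfg$mito_fraction_range[1],
                              cfg$mito_fraction_range[2])

    # per (cluster, condition) group: shifted relative gene weights
    grp <- interaction(truth$cluster, truth$condition, drop = TRUE)
    mu <- matrix(0, nrow = n, ncol = cfg$n_genes)
    for (g in levels(grp)) {
      rows <- which(grp == g)
      cl <- truth$cluster[rows[1]]
      cond <- truth$condition[rows[1]]
      lfc <- numeric(cfg$n_genes)
      spec <- cfg$cluster_spec[[cl]]
      lfc[match(spec$markers, genes)] <- spec$log2fc
      lfc[match(cfg$program_spec$genes, genes)] <-
        lfc[match(cfg$program_spec$genes, genes)] + cfg$program_spec$effect[[cond]]
      w <- base * 2^lfc
      p <- w[!mito] / sum(w[!mito])
      p_m <- base[mito] / sum(base[mito])
      mu[rows, !mito] <- outer(totals[rows] * (1 - mito_frac[rows]), p)
      mu[rows, mito] <- outer(totals[rows] * mito_frac[rows], p_m)
    }
    counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = cfg$dispersion),
                     nrow = n, ncol = cfg$n_genes)
  })

  features <- data.frame(id = genes, name = genes, type = "Gene Expression",
                         stringsAsFactors = FALSE)
  count_matrix(counts, truth$barcode, features, condition = truth$condition)
}

#' Simulate a full experiment and write it as a 10x triplet
#'
#' Combines gene-expression and hashtag features into one matrix, writes
#' it with [write_10x_mtx()] and the ground truth as TSV.
#'
#' @param cfg a [synth_config()].
#' @param out_dir output directory.
#' @return list with `dir`, `truth_path` and the `truth` data.frame.
#' @export
simulate_experiment <- function(cfg, out_dir) {
  hto <- simulate_hto(cfg)
  expr <- simulate_expression(cfg, hto$truth)
  combined <- count_matrix(
    cbind(expr$counts, hto$matrix$counts),
    expr$barcodes,
    rbind(expr$features, hto$matrix$features),
    condition = hto$truth$condition
  )
  write_10x_mtx(combined, out_dir)
  truth_path <- file.path(out_dir, "truth.tsv")
  write_table(hto$truth, truth_path)
  list(dir = out_dir, truth_path = truth_path, truth = hto$truth)
}
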