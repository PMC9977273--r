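# Cell- and gene-level quality control. Thresholds follow the strict
# "less than" / "more than" wording: boundary cells are kept. The
# pipeline order is fixed: cell filter first, then gene exclusions.

#' Default gene-family exclusion patterns (mouse naming)
#'
#' Regular expressions matching mitochondrial genes, ribosomal protein
#' genes, and TCR alpha/beta V(D)J segment genes.
#' @export
default_exclusion_patterns <- function() {
  c(mito = "^mt-", ribo = "^Rp[sl]", tcr_vdj = "^Tr[ab][vdj]")
}

#' Per-cell QC metrics
#'
#' Computes, on raw counts over gene-expression features, each cell's
#' transcript total and mitochondrial fraction (genes matched by a name
#' pattern), plus per-gene detection counts. Cells with a zero total get
#' fraction 0 and a warning flag.
#'
#' @param m a `CountMatrix` with gene-expression features.
#' @param mito_pattern regex selecting mitochondrial genes by name.
#' @return a `QCReport`: `cell_metrics` (data.frame `barcode`, `total`,
#'   `mito_fraction`, `zero_total`), `gene_detection` (named integer),
#'   and empty masks/tallies to be filled by the filters.
#' @export
compute_cell_metrics <- function(m, mito_pattern = "^mt-") {
  g <- gene_part(m)
  total <- Matrix::rowSums(g$counts)
  mito_idx <- grepl(mito_pattern, g$features$name)
  mito <- if (any(mito_idx)) Matrix::rowSums(g$counts[, mito_idx, drop = FALSE]) else
    numeric(n_cells(g))
  zero <- total == 0
  if (any(zero)) warning(sum(zero), " cell(s) with zero total; mito fraction set to 0")
  frac <- ifelse(zero, 0, mito / pmax(total, 1))
  detection <- Matrix::colSums(g$counts > 0)
  names(detection) <- g$features$id
  structure(list(
    cell_metrics = data.frame(barcode = g$barcodes, total = total,
                              mito_fraction = frac, zero_total = zero,
                              stringsAsFactors = FALSE),
    gene_detection = detection,
    tallies = integer(0)
  ), class = "QCReport")
}

#' Filter cells on transcript total and mitochondrial fraction
#'
#' Drops a cell iff `total < min_transcripts` OR
#' `mito_fraction > max_mito` (strict inequalities; boundary cells are
#' kept). Defaults are the first-pass thresholds (200 transcripts, 15%
#' mitochondrial); the re-filter uses `max_mito = 0.075` and the
#' human-atlas settings `max_mito = 0.10`.
#'
#' @param m a `CountMatrix`.
#' @param report a `QCReport` from [compute_cell_metrics()] aligned to
#'   `m`; recomputed when `NULL`.
#' @param min_transcripts minimum transcript total.
#' @param max_mito maximum mitochondrial fraction.
#' @param doublet_flags optional named logical vector (external doublet
#'   calls); when given, cells flagged TRUE with above-average totals are
#'   also dropped (the composite atlas rule).
#' @return list: `matrix` (filtered `CountMatrix`), `keep` (named
#'   logical), `tallies` of removals by rule.
#' @export
filter_cells <- function(m, report = NULL, min_transcripts = 200,
                         max_mito = 0.15, doublet_flags = NULL) {
  if (is.null(report)) report <- compute_cell_metrics(m)
  cm <- report$cell_metrics
  if (!identical(cm$barcode, m$barcodes))
    stop("report is not aligned to the matrix", call. = FALSE)
  low <- cm$total < min_transcripts
  high_mito <- cm$mito_fraction > max_mito
  dbl <- rep(FALSE, n_cells(m))
  if (!is.null(doublet_flags))
    dbl <- unname(doublet_flags[m$barcodes]) & cm$total > mean(cm$total)
  drop <- low | high_mito | dbl
  if (all(drop)) stop("empty output: all cells dropped by the cell filter",
                      call. = FALSE)
  keep <- !drop
  names(keep) <- m$barcodes
  list(matrix = subset_cells(m, keep),
       keep = keep,
       tallies = c(low_transcripts = sum(low),
                   high_mito = sum(high_mito & !low),
                   flagged_doublet = sum(dbl & !low & !high_mito),
                   removed = sum(drop), kept = sum(keep)))
}

#' Exclude gene families and rarely detected genes
#'
#' Removes genes whose name matches any exclusion pattern (defaults:
#' mitochondrial, ribosomal, TCR V(D)J families) or whose transcripts are
#' detected in fewer than `min_cells` cells (strict; a gene seen in
#' exactly `min_cells` cells is kept). Applies to gene-expression
#' features only; antibody-capture features pass through untouched.
#'
#' @param m a `CountMatrix`.
#' @param exclusion_patterns named character vector of regexes.
#' @param min_cells minimum number of cells a gene must be detected in.
#' @return list: `matrix`, `keep` (per gene-expression feature), `tallies`.
#' @export
filter_genes <- function(m, exclusion_patterns = default_exclusion_patterns(),
                         min_cells = 3) {
  is_gene <- m$features$type == "Gene Expression"
  name <- m$features$name
  pattern_hit <- rep(FALSE, n_features(m))
  per_pattern <- integer(length(exclusion_patterns))
  names(per_pattern) <- names(exclusion_patterns)
  for (i in seq_along(exclusion_patterns)) {
    hit <- grepl(exclusion_patterns[[i]], name) & is_gene
    per_pattern[i] <- sum(hit)
    pattern_hit <- pattern_hit | hit
  }
  detection <- Matrix::colSums(m$counts > 0)
  rare <- is_gene & detection < min_cells
  drop <- is_gene & (pattern_hit | rare)
  keep <- !drop
  list(matrix = subset_features(m, keep),
       keep = keep[is_gene],
       tallies = c(per_pattern, rare = sum(rare & !pattern_hit),
                   removed = sum(drop), kept = sum(keep & is_gene)))
}
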