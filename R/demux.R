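# Hashtag demultiplexing by histogram valley detection.
#
# For each hashtag, tally how many cells carry exactly c reads of it
# (c = 0..max observed), smooth the histogram with a centered sliding
# window, and find the end of the initial slope by gradient descent:
# ascend from bin 0 to the first local maximum, then move right while the
# next smoothed value is strictly lower. The final index is the read
# limit; a cell is associated with every hashtag whose raw count reaches
# its limit, one association makes a singlet, several a doublet.

#' Per-hashtag count histograms over pre-filtered cells
#'
#' Cells whose gene-expression transcript total falls below
#' `min_transcripts` are removed before tallying (default 200). Each
#' histogram spans read counts 0..max observed for that hashtag;
#' `bin_counts[c + 1]` is the number of surviving cells with exactly `c`
#' reads.
#'
#' @param hto `CountMatrix` whose features are all antibody-capture.
#' @param gene_totals named per-cell transcript totals aligned to the
#'   barcodes of `hto` (see [gene_totals()]).
#' @param min_transcripts pre-filter threshold; cells with fewer
#'   transcripts are excluded.
#' @return named list of `HashtagHistogram` objects (`hashtag_id`,
#'   `bin_counts`, `smoothed = NULL`, `n_cells`).
#' @export
build_histograms <- function(hto, gene_totals, min_transcripts = 200) {
  if (!all(hto$features$type == "Antibody Capture"))
    stop("hto must contain only antibody-capture features", call. = FALSE)
  if (is.null(names(gene_totals)) || !setequal(names(gene_totals), hto$barcodes))
    stop("alignment error: gene_totals names do not match hto barcodes",
         call. = FALSE)
  gene_totals <- gene_totals[hto$barcodes]
  keep <- gene_totals >= min_transcripts
  if (!any(keep))
    stop("empty input: no cell passes the ", min_transcripts,
         "-transcript pre-filter", call. = FALSE)
  counts <- hto$counts[keep, , drop = FALSE]
  out <- lapply(seq_len(ncol(counts)), function(j) {
    v <- counts[, j]
    bins <- tabulate(v + 1L, nbins = max(v) + 1L)
    structure(list(hashtag_id = hto$features$id[j], bin_counts = bins,
                   smoothed = NULL, n_cells = sum(bins)),
              class = "HashtagHistogram")
  })
  names(out) <- hto$features$id
  out
}

#' Smooth a hashtag histogram with a centered sliding window
#'
#' `smoothed[c]` is the arithmetic mean of the raw bins within the
#' centered window of the given size, truncated at the array boundaries;
#' raw bins are preserved.
#'
#' @param h a `HashtagHistogram`.
#' @param window odd window size >= 1 (default 5).
#' @return the histogram with its `smoothed` field filled.
#' @export
smooth_histogram <- function(h, window = 5) {
  if (window < 1 || window %% 2 == 0)
    stop("parameter error: window must be odd and >= 1", call. = FALSE)
  x <- h$bin_counts
  n <- length(x)
  hw <- (window - 1) %/% 2
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - hw, 1L)
  hi <- pmin(seq_len(n) + hw, n)
  h$smoothed <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  h
}

#' Read limit of a smoothed histogram by gradient descent
#'
#' Starting position: ascend from bin 0 while the next smoothed value is
#' strictly higher, stopping at the first local maximum (with
#' `start = "zero"` the descent starts at bin 0 regardless). From there
#' the cursor moves right while the next value is strictly lower; the
#' returned limit is the read count (0-based bin index) where it stops.
#' Plateaus stop both the ascent and the descent.
#'
#' @param h a `HashtagHistogram` with `smoothed` present.
#' @param start `"first_local_max"` (default) or `"zero"`.
#' @return integer read limit in `[0, C_max]`.
#' @export
find_limit <- function(h, start = c("first_local_max", "zero")) {
  start <- match.arg(start)
  s <- h$smoothed
  if (is.null(s)) stop("histogram has no smoothed values; run smooth_histogram()",
                       call. = FALSE)
  n <- length(s)
  if (n == 0) stop("empty histogram", call. = FALSE)
  i <- 1L
  if (start == "first_local_max")
    while (i < n && s[i + 1] > s[i]) i <- i + 1L
  while (i < n && s[i + 1] < s[i]) i <- i + 1L
  i - 1L # bin index -> read count
}

#' Assign cells to samples given per-hashtag read limits
#'
#' A cell passing the transcript pre-filter is associated with hashtag
#' `h` iff its raw count for `h` is at least `limits[h]` (inclusive;
#' `exclusive = TRUE` switches to strictly greater). Exactly one
#' association makes a singlet, two or more a doublet, none leaves the
#' cell unassigned. A limit of 0 would associate every cell and is
#' flagged low-quality with a warning.
#'
#' @param hto antibody-capture `CountMatrix`.
#' @param limits named integer vector, one limit per hashtag feature.
#' @param min_transcripts transcript pre-filter (cells below it are
#'   reported in `removed_low_count`).
#' @param gene_totals named per-cell transcript totals.
#' @param exclusive use `> limit` instead of `>= limit`.
#' @return a `DemuxResult`: `limits`, `calls` (data.frame `barcode`,
#'   `call` in singlet/doublet/unassigned/removed_low_count, `sample`,
#'   `samples`), `removed_low_count`, `low_quality_hashtags`, `tallies`.
#' @export
assign_cells <- function(hto, limits, min_transcripts = 200, gene_totals,
                         exclusive = FALSE) {
  ids <- hto$features$id
  if (!all(ids %in% names(limits)))
    stop("configuration error: no limit for hashtag(s): ",
         paste(setdiff(ids, names(limits)), collapse = ", "), call. = FALSE)
  limits <- limits[ids]
  low_q <- names(limits)[limits == 0]
  if (length(low_q))
    warning("limit 0 for hashtag(s) ", paste(low_q, collapse = ", "),
            ": every cell would be associated; flagged low-quality")
  gene_totals <- gene_totals[hto$barcodes]
  surviving <- gene_totals >= min_transcripts

  cmp <- if (exclusive) `>` else `>=`
  assoc <- cmp(as.matrix(hto$counts),
               matrix(limits, nrow = n_cells(hto), ncol = length(ids), byrow = TRUE))
  n_assoc <- rowSums(assoc)
  call <- ifelse(!surviving, "removed_low_count",
          ifelse(n_assoc == 1, "singlet",
          ifelse(n_assoc >= 2, "doublet", "unassigned")))
  sample_lab <- ifelse(call == "singlet", ids[max.col(assoc, ties.method = "first")],
                       NA_character_)
  samples <- vapply(seq_len(nrow(assoc)), function(i)
    if (call[i] %in% c("singlet", "doublet"))
      paste(ids[assoc[i, ]], collapse = ";") else NA_character_, "")

  calls <- data.frame(barcode = hto$barcodes, call = call,
                      sample = sample_lab, samples = samples,
                      stringsAsFactors = FALSE)
  tallies <- c(singlet = sum(call == "singlet"),
               doublet = sum(call == "doublet"),
               unassigned = sum(call == "unassigned"),
               removed_low_count = sum(call == "removed_low_count"))
  structure(list(limits = limits, calls = calls,
                 removed_low_count = hto$barcodes[!surviving],
                 low_quality_hashtags = low_q, tallies = tallies),
            class = "DemuxResult")
}

#' @export
print.DemuxResult <- function(x, ...) {
  cat("DemuxResult:", paste(sprintf("%s=%d", names(x$tallies), x$tallies),
                            collapse = ", "), "\n")
  cat("limits:", paste(sprintf("%s:%d", names(x$limits), x$limits),
                       collapse = ", "), "\n")
  invisible(x)
}

#' Demultiplex a combined gene + hashtag matrix
#'
#' Convenience wrapper running the full demultiplexing path: transcript
#' pre-filter, per-hashtag histograms, sliding-window smoothing, gradient
#' descent limits, and cell assignment with doublet exclusion.
#'
#' @param m `CountMatrix` holding gene-expression and antibody-capture
#'   features together.
#' @param window smoothing window size (odd, default 5).
#' @param min_transcripts transcript pre-filter (default 200).
#' @param start descent start rule, see [find_limit()].
#' @param exclusive association rule, see [assign_cells()].
#' @return a `DemuxResult`.
#' @export
demux_hashtags <- function(m, window = 5, min_transcripts = 200,
                           start = "first_local_max", exclusive = FALSE) {
  hto <- hashtag_part(m)
  if (n_features(hto) == 0) stop("no antibody-capture features in matrix", call. = FALSE)
  totals <- gene_totals(m)
  hists <- build_histograms(hto, totals, min_transcripts = min_transcripts)
  hists <- lapply(hists, smooth_histogram, window = window)
  limits <- vapply(hists, find_limit, 0L, start = start)
  res <- assign_cells(hto, limits, min_transcripts = min_transcripts,
                      gene_totals = totals, exclusive = exclusive)
  res$histograms <- hists
  res
}
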