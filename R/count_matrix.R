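#' @importFrom methods as is
NULL

# canonical 10x feature type strings; lax synonyms accepted on input
.FEATURE_TYPES <- c("Gene Expression", "Antibody Capture")

.normalize_feature_type <- function(x) {
  key <- gsub("[-_ ]+", " ", tolower(trimws(x)))
  out <- ifelse(key == "gene expression", "Gene Expression",
         ifelse(key == "antibody capture", "Antibody Capture", NA_character_))
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    stop("unknown feature type(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  out
}

#' Construct a cell x feature count matrix
#'
#' `CountMatrix` is the container every pipeline stage consumes: a sparse
#' cells x features matrix of non-negative integer counts, barcode
#' identifiers for the rows, and a feature table (`id`, `name`, `type`)
#' for the columns, where `type` is `"Gene Expression"` or
#' `"Antibody Capture"` (hashtags).
#'
#' @param counts matrix coercible to `dgCMatrix`, cells in rows.
#' @param barcodes character vector of unique cell identifiers, one per row.
#' @param features data.frame with columns `id`, `name` and optionally
#'   `type` (defaults to `"Gene Expression"`), one row per column of
#'   `counts`.
#' @param condition optional per-cell label (length `nrow(counts)`).
#' @return an object of class `CountMatrix`.
#' @export
count_matrix <- function(counts, barcodes, features, condition = NULL) {
  if (!methods::is(counts, "sparseMatrix"))
    counts <- Matrix::Matrix(as.matrix(counts), sparse = TRUE)
  counts <- as(as(as(counts, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (is.null(features$type)) features$type <- "Gene Expression"
  features <- data.frame(
    id = as.character(features$id),
    name = as.character(features$name),
    type = .normalize_feature_type(features$type),
    stringsAsFactors = FALSE
  )
  obj <- structure(
    list(counts = counts, barcodes = as.character(barcodes),
         features = features, condition = condition),
    class = "CountMatrix"
  )
  validate_count_matrix(obj)
}

#' @rdname count_matrix
#' @param x a `CountMatrix`.
#' @export
validate_count_matrix <- function(x) {
  counts <- x$counts
  if (nrow(counts) != length(x$barcodes))
    stop("number of matrix rows (", nrow(counts), ") differs from number of barcodes (",
         length(x$barcodes), ")", call. = FALSE)
  if (ncol(counts) != nrow(x$features))
    stop("number of matrix columns (", ncol(counts), ") differs from number of features (",
         nrow(x$features), ")", call. = FALSE)
  if (anyDuplicated(x$barcodes))
    stop("barcode identifiers are not unique", call. = FALSE)
  if (anyDuplicated(x$features$id))
    stop("feature identifiers are not unique", call. = FALSE)
  v <- counts@x
  if (length(v)) {
    if (any(v < 0)) stop("negative counts are not allowed", call. = FALSE)
    if (max(abs(v - round(v))) > 1e-8) stop("fractional counts are not allowed", call. = FALSE)
  }
  if (!is.null(x$condition) && length(x$condition) != nrow(counts))
    stop("condition labels must align with cells", call. = FALSE)
  dimnames(x$counts) <- list(x$barcodes, x$features$id)
  x
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

#' Number of cells / features in a CountMatrix
#' @param m a `CountMatrix`.
#' @export
n_cells <- function(m) nrow(m$counts)

#' @rdname n_cells
#' @export
n_features <- function(m) ncol(m$counts)

#' @export
print.CountMatrix <- function(x, ...) {
  tab <- table(x$features$type)
  cat(sprintf("CountMatrix: %d cells x %d features (%s)\n",
              n_cells(x), n_features(x),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Subset a CountMatrix by cells or by features
#'
#' @param m a `CountMatrix`.
#' @param idx integer, logical or barcode/feature-id index.
#' @return a `CountMatrix` restricted to the selected rows / columns.
#' @export
subset_cells <- function(m, idx) {
  if (is.character(idx)) idx <- match(idx, m$barcodes)
  if (is.logical(idx)) idx <- which(idx)
  count_matrix(m$counts[idx, , drop = FALSE], m$barcodes[idx], m$features,
               condition = if (is.null(m$condition)) NULL else m$condition[idx])
}

#' @rdname subset_cells
#' @export
subset_features <- function(m, idx) {
  if (is.character(idx)) idx <- match(idx, m$features$id)
  if (is.logical(idx)) idx <- which(idx)
  count_matrix(m$counts[, idx, drop = FALSE], m$barcodes,
               m$features[idx, , drop = FALSE], condition = m$condition)
}

#' Split a CountMatrix into its gene-expression or antibody-capture part
#' @param m a `CountMatrix`.
#' @export
gene_part <- function(m) subset_features(m, m$features$type == "Gene Expression")

#' @rdname gene_part
#' @export
hashtag_part <- function(m) subset_features(m, m$features$type == "Antibody Capture")

#' Per-cell transcript totals over gene-expression features
#'
#' The totals driving the 200-transcript pre-filter; named by barcode.
#' @param m a `CountMatrix`.
#' @return named numeric vector of per-cell totals.
#' @export
gene_totals <- function(m) {
  keep <- m$features$type == "Gene Expression"
  tot <- Matrix::rowSums(m$counts[, keep, drop = FALSE])
  names(tot) <- m$barcodes
  tot
}
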