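# 10x triplet convention: on disk the matrix is features x cells with 1-based
# Matrix Market indices; in memory we expose cells x features with ordinary
# R (1-based) indexing. read/write below own that boundary.

.find_10x_file <- function(directory, bases) {
  for (b in bases) for (suffix in c("", ".gz")) {
    p <- file.path(directory, paste0(b, suffix))
    if (file.exists(p)) return(p)
  }
  stop("input error: no file ", paste(bases, collapse = " / "),
       " (plain or .gz) in ", directory, call. = FALSE)
}

.read_tsv_noheader <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) return(data.frame(V1 = character(0)))
  utils::read.delim(text = lines, header = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character", quote = "")
}

#' Read a 10x-style Matrix Market triplet directory
#'
#' Expects `matrix.mtx`, `features.tsv` (or `genes.tsv`) and `barcodes.tsv`,
#' each optionally gzipped. The on-disk matrix is features x cells; the
#' returned [count_matrix()] is cells x features. A third features column,
#' when present, is parsed as the feature type; otherwise all features are
#' typed `"Gene Expression"`.
#'
#' @param directory path containing the triplet.
#' @return a `CountMatrix`.
#' @export
read_10x_mtx <- function(directory) {
  if (!dir.exists(directory))
    stop("input error: directory not found: ", directory, call. = FALSE)
  mtx_path <- .find_10x_file(directory, "matrix.mtx")
  feat_path <- .find_10x_file(directory, c("features.tsv", "genes.tsv"))
  bc_path <- .find_10x_file(directory, "barcodes.tsv")

  con <- if (grepl("\\.gz$", mtx_path)) gzfile(mtx_path) else file(mtx_path)
  m_disk <- Matrix::readMM(con) # features x cells

  feats <- .read_tsv_noheader(feat_path)
  if (ncol(feats) < 2) feats$V2 <- feats$V1
  barcodes <- .read_tsv_noheader(bc_path)$V1

  if (nrow(feats) != nrow(m_disk))
    stop("format error: features table has ", nrow(feats),
         " rows but matrix header declares ", nrow(m_disk), " features",
         call. = FALSE)
  if (length(barcodes) != ncol(m_disk))
    stop("format error: barcodes table has ", length(barcodes),
         " rows but matrix header declares ", ncol(m_disk), " cells",
         call. = FALSE)

  features <- data.frame(id = feats[[1]], name = feats[[2]],
                         type = if (ncol(feats) >= 3) feats[[3]] else "Gene Expression",
                         stringsAsFactors = FALSE)
  count_matrix(Matrix::t(m_disk), barcodes, features)
}

.write_maybe_gz <- function(lines, path, gzip) {
  con <- if (gzip) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
}

#' Write a CountMatrix as a 10x-style triplet
#'
#' Writes `matrix.mtx`, `features.tsv`, `barcodes.tsv` (gzipped when
#' `gzip = TRUE`) in the features x cells orientation with 1-based Matrix
#' Market indices. Explicit zeros are dropped before writing.
#'
#' @param m a `CountMatrix`.
#' @param directory output directory, created if needed.
#' @param gzip write `.gz` files instead of plain text.
#' @return the directory, invisibly.
#' @export
write_10x_mtx <- function(m, directory, gzip = FALSE) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(directory))
    stop("I/O error: cannot create directory ", directory, call. = FALSE)
  suffix <- if (gzip) ".gz" else ""

  disk <- Matrix::drop0(Matrix::t(m$counts)) # features x cells
  mtx_tmp <- tempfile(fileext = ".mtx")
  Matrix::writeMM(disk, mtx_tmp)
  .write_maybe_gz(readLines(mtx_tmp), file.path(directory, paste0("matrix.mtx", suffix)), gzip)
  unlink(mtx_tmp)

  feat_lines <- paste(m$features$id, m$features$name, m$features$type, sep = "\t")
  .write_maybe_gz(feat_lines, file.path(directory, paste0("features.tsv", suffix)), gzip)
  .write_maybe_gz(m$barcodes, file.path(directory, paste0("barcodes.tsv", suffix)), gzip)
  invisible(directory)
}

#' Read gene signatures from a GMT file
#'
#' One signature per tab-separated line: name, description, then gene
#' names. Duplicate genes within a line are removed, order preserved.
#'
#' @param path GMT file (plain or gzipped).
#' @return named list of `GeneSignature` objects (`name`, `description`,
#'   `genes`).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("input error: no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sigs <- lapply(seq_along(lines), function(i) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop("format error: GMT line ", i, " has fewer than 3 fields", call. = FALSE)
    genes <- unique(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    gene_signature(fields[[1]], genes, description = fields[[2]])
  })
  names(sigs) <- vapply(sigs, `[[`, "", "name")
  sigs
}

#' Construct a gene signature
#' @param name signature name.
#' @param genes character vector of gene names (deduplicated, order kept).
#' @param description free-text description.
#' @export
gene_signature <- function(name, genes, description = "") {
  genes <- unique(as.character(genes))
  if (length(genes) == 0) stop("signature '", name, "' is empty", call. = FALSE)
  structure(list(name = name, description = description, genes = genes),
            class = "GeneSignature")
}

#' Write gene signatures to a GMT file
#' @param sigs list of `GeneSignature` objects.
#' @param path output path.
#' @export
write_gmt <- function(sigs, path) {
  lines <- vapply(sigs, function(s)
    paste(c(s$name, if (nzchar(s$description)) s$description else ".", s$genes),
          collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Write a tabular report as TSV
#'
#' Header plus one line per row; numeric values keep full double
#' precision (>= 6 significant digits round-trip).
#'
#' @param rows a data.frame.
#' @param path output path.
#' @export
write_table <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  ok <- tryCatch({
    utils::write.table(rows, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, na = "NA")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("I/O error writing ", path, ": ", conditionMessage(ok), call. = FALSE)
  invisible(path)
}
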