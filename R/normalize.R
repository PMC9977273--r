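# Log normalization, variable-gene selection and covariate-regressed
# scaling. The normalized container keeps the raw counts alongside the
# log values because the mean-variance trend for variable-gene ranking is
# fit on raw counts.

#' Log-normalize a count matrix
#'
#' `value[c, g] = ln(1 + count[c, g] * scale_factor / total[c])` with the
#' per-cell total taken over all retained genes. For a cell with all its
#' genes retained, `sum(expm1(value))` equals `scale_factor` exactly.
#'
#' @param m a `CountMatrix` of gene-expression features (post QC).
#' @param scale_factor library-size target (default 1e4).
#' @return a `NormalizedMatrix`: `values` (sparse cells x genes log
#'   expression), `counts` (raw), `genes`, `barcodes`, `scale_factor`.
#' @export
log_normalize <- function(m, scale_factor = 1e4) {
  g <- gene_part(m)
  totals <- Matrix::rowSums(g$counts)
  if (any(totals == 0))
    stop("zero-total cell(s) present; filter cells before normalizing",
         call. = FALSE)
  values <- Matrix::Diagonal(x = scale_factor / totals) %*% g$counts
  values <- as(values, "CsparseMatrix")
  values@x <- log1p(values@x)
  dimnames(values) <- list(g$barcodes, g$features$id)
  structure(list(values = values, counts = g$counts, genes = g$features$id,
                 barcodes = g$barcodes, scale_factor = scale_factor,
                 condition = g$condition),
            class = "NormalizedMatrix")
}

#' Rank genes by standardized variance and keep the most variable
#'
#' Per-gene mean and variance are computed on raw counts; a loess trend
#' of log10(variance) on log10(mean) predicts the expected standard
#' deviation; counts are standardized against it (clipped at
#' `sqrt(n_cells)`) and genes are ranked by the variance of the clipped
#' standardized values. Ties break deterministically by gene identifier.
#' With `method = "dispersion"` the simpler variance/mean ratio ranks
#' instead.
#'
#' @param nm a `NormalizedMatrix`.
#' @param n_features number of genes to return (<= gene count).
#' @param method `"vst"` (trend-standardized variance, default) or
#'   `"dispersion"`.
#' @param loess_span span of the trend fit.
#' @return character vector of the `n_features` top-ranked gene ids, in
#'   rank order.
#' @export
select_variable_genes <- function(nm, n_features, method = c("vst", "dispersion"),
                                  loess_span = 0.3) {
  method <- match.arg(method)
  counts <- nm$counts
  n_genes <- ncol(counts)
  if (n_features > n_genes)
    stop("parameter error: n_features (", n_features, ") exceeds gene count (",
         n_genes, ")", call. = FALSE)
  n <- nrow(counts)
  mu <- Matrix::colMeans(counts)
  ex2 <- Matrix::colMeans(counts^2)
  v <- (ex2 - mu^2) * n / (n - 1)

  score <- if (method == "vst") {
    sd_exp <- sqrt(v)
    fit_on <- v > 0 & mu > 0
    if (sum(fit_on) >= 10) {
      fit <- stats::loess(log10(v[fit_on]) ~ log10(mu[fit_on]), span = loess_span)
      sd_exp[fit_on] <- sqrt(10^stats::predict(fit))
    }
    vapply(seq_len(n_genes), function(j) {
      if (v[j] == 0 || sd_exp[j] == 0) return(0)
      z <- pmin((counts[, j] - mu[j]) / sd_exp[j], sqrt(n))
      sum(z^2) / (n - 1)
    }, 0)
  } else {
    ifelse(mu > 0, v / mu, 0)
  }
  ord <- order(-score, nm$genes)
  nm$genes[ord[seq_len(n_features)]]
}

#' Scale genes to unit variance after regressing out covariates
#'
#' Per gene: ordinary least squares of log expression on the covariates
#' plus an intercept; residuals are standardized to mean 0, variance 1
#' and clipped to `[-clip, clip]`. Collinear covariate columns are
#' dropped with a warning. A gene whose residuals are constant is
#' reported as all zeros.
#'
#' @param nm a `NormalizedMatrix`.
#' @param genes gene ids to scale (e.g. the variable genes).
#' @param covariates optional numeric matrix/data.frame of per-cell
#'   scores (cell-cycle S and G2/M scores in the reference workflow).
#' @param clip clipping bound for the scaled values (default 10).
#' @return dense matrix, cells x length(genes).
#' @export
scale_and_regress <- function(nm, genes = nm$genes, covariates = NULL, clip = 10) {
  Y <- as.matrix(nm$values[, genes, drop = FALSE])
  n <- nrow(Y)
  if (!is.null(covariates)) {
    X <- cbind(intercept = 1, as.matrix(covariates))
    qr_x <- qr(X)
    if (qr_x$rank < ncol(X)) {
      drop_cols <- qr_x$pivot[(qr_x$rank + 1):ncol(X)]
      warning("dropping collinear covariate column(s): ",
              paste(colnames(X)[drop_cols], collapse = ", "))
      X <- X[, -drop_cols, drop = FALSE]
      qr_x <- qr(X)
    }
    Y <- Y - X %*% qr.coef(qr_x, Y)
  }
  ctr <- sweep(Y, 2, colMeans(Y))
  sdv <- sqrt(colSums(ctr^2) / (n - 1))
  constant <- sdv < 1e-12
  sdv[constant] <- 1
  out <- sweep(ctr, 2, sdv, "/")
  out[, constant] <- 0
  out[out > clip] <- clip
  out[out < -clip] <- -clip
  rownames(out) <- nm$barcodes
  colnames(out) <- genes
  out
}
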