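# Signature scoring and preranked gene-set enrichment.
#
# Module scores follow the expression-bin-matched control convention:
# genes are binned by dataset-average expression, each signature gene
# draws control genes from its own bin, and the score is the mean
# expression of the signature minus the mean expression of the control
# pool. GSEA uses the weighted running-sum statistic on a list ranked by
# log2 fold change, with exact ties placed in random order, and a
# permutation null of random same-size gene sets.

#' Expression-bin-matched module score
#'
#' Genes are cut into `n_bins` equal-frequency bins by their average
#' log-normalized expression across all cells. For each signature gene,
#' up to `n_ctrl` control genes are drawn (without replacement, seeded)
#' from its bin, excluding signature genes. The per-cell score is the
#' mean expression over signature genes minus the mean over the pooled
#' control genes. Signature genes absent from the matrix are dropped
#' first.
#'
#' @param nm a `NormalizedMatrix`.
#' @param sig a `GeneSignature`.
#' @param n_bins number of expression bins (default 24).
#' @param n_ctrl controls drawn per signature gene (default 100).
#' @param seed RNG seed for the control draw.
#' @param ctrl_genes optional explicit control pool overriding the draw.
#' @return data.frame `barcode`, `score`, with attributes `signature`,
#'   `n_bins`, `n_ctrl`, `seed`, `control_genes`.
#' @export
module_score <- function(nm, sig, n_bins = 24, n_ctrl = 100, seed = 1,
                         ctrl_genes = NULL) {
  genes <- intersect(sig$genes, nm$genes)
  if (length(genes) == 0)
    stop("signature '", sig$name, "' has no genes detected in the matrix",
         call. = FALSE)
  if (is.null(ctrl_genes)) {
    avg <- Matrix::colMeans(nm$values)
    names(avg) <- nm$genes
    n_genes <- length(avg)
    bin <- ceiling(rank(avg, ties.method = "first") * n_bins / n_genes)
    ctrl_genes <- withr::with_seed(seed, {
      unique(unlist(lapply(genes, function(g) {
        pool <- nm$genes[bin == bin[[match(g, nm$genes)]]]
        pool <- setdiff(pool, sig$genes)
        if (length(pool) == 0) return(character(0))
        sample(pool, min(n_ctrl, length(pool)))
      })))
    })
  }
  sig_mean <- Matrix::rowMeans(nm$values[, genes, drop = FALSE])
  ctrl_mean <- if (length(ctrl_genes))
    Matrix::rowMeans(nm$values[, ctrl_genes, drop = FALSE]) else sig_mean
  out <- data.frame(barcode = nm$barcodes, score = as.numeric(sig_mean - ctrl_mean),
                    stringsAsFactors = FALSE)
  attr(out, "signature") <- sig$name
  attr(out, "n_bins") <- n_bins
  attr(out, "n_ctrl") <- n_ctrl
  attr(out, "seed") <- seed
  attr(out, "control_genes") <- ctrl_genes
  out
}

#' Rank genes by log2 fold change between two cell groups
#'
#' Per gene: `log2((mean(expm1(A)) + pc) / (mean(expm1(B)) + pc))` on
#' the log-normalized values. Genes are sorted by decreasing statistic;
#' exact ties are placed in random order driven by `tie_seed`.
#'
#' @param nm a `NormalizedMatrix`.
#' @param group_a,group_b disjoint, non-empty barcode vectors (or
#'   logical/integer indices over cells).
#' @param pseudocount added to both group means (default 1).
#' @param tie_seed seed for the tie permutation.
#' @return a `RankedList`: data.frame `gene`, `stat` in rank order, with
#'   attribute `tie_seed`.
#' @export
fold_change <- function(nm, group_a, group_b, pseudocount = 1, tie_seed = 1) {
  to_idx <- function(g) {
    if (is.character(g)) match(g, nm$barcodes)
    else if (is.logical(g)) which(g)
    else as.integer(g)
  }
  ia <- to_idx(group_a)
  ib <- to_idx(group_b)
  if (length(ia) == 0 || length(ib) == 0)
    stop("both groups must be non-empty", call. = FALSE)
  if (anyNA(ia) || anyNA(ib)) stop("unknown barcodes in group", call. = FALSE)
  if (length(intersect(ia, ib))) stop("groups must be disjoint", call. = FALSE)
  ma <- Matrix::colMeans(expm1(nm$values[ia, , drop = FALSE]))
  mb <- Matrix::colMeans(expm1(nm$values[ib, , drop = FALSE]))
  stat <- log2((ma + pseudocount) / (mb + pseudocount))
  tie_key <- withr::with_seed(tie_seed, sample.int(length(stat)))
  ord <- order(-stat, tie_key)
  out <- data.frame(gene = nm$genes[ord], stat = stat[ord],
                    stringsAsFactors = FALSE)
  attr(out, "tie_seed") <- tie_seed
  class(out) <- c("RankedList", "data.frame")
  out
}

# running-sum enrichment score on an already-ordered statistic vector
.gsea_running_es <- function(stat, member, weight_exponent = 1) {
  N <- length(stat)
  S <- sum(member)
  if (S == 0) stop("signature has no genes in the ranked list", call. = FALSE)
  if (S == N) stop("signature covers the whole ranked list; decrement undefined",
                   call. = FALSE)
  w <- abs(stat)^weight_exponent
  denom <- sum(w[member])
  inc <- numeric(N)
  if (denom > 0) inc[member] <- w[member] / denom else inc[member] <- 1 / S
  inc[!member] <- -1 / (N - S)
  running <- cumsum(inc)
  running[which.max(abs(running))]
}

#' Preranked GSEA with a permutation null
#'
#' Weighted Kolmogorov-Smirnov-style running sum over the ranked list:
#' at signature positions the sum rises by `|stat|^weight_exponent`
#' normalized over signature genes, elsewhere it falls by
#' `1/(N - |S|)`; the enrichment score ES is the signed maximum
#' deviation. The null distribution samples random gene sets of the same
#' size; `p = (1 + #{|ES_null| >= |ES|}) / (n_permutations + 1)` and
#' `NES = ES / mean(|ES_null|)` over null scores of matching sign.
#'
#' @param rl a `RankedList` from [fold_change()].
#' @param sig a `GeneSignature`.
#' @param weight_exponent exponent on the ranking statistic (default 1).
#' @param n_permutations size of the null sample (default 1000).
#' @param seed RNG seed for the null draw.
#' @return a `GSEAResult`: `es`, `nes`, `pval`, `size`,
#'   `n_permutations`, `seed`.
#' @export
gsea_preranked <- function(rl, sig, weight_exponent = 1,
                           n_permutations = 1000, seed = 1) {
  member <- rl$gene %in% sig$genes
  es <- .gsea_running_es(rl$stat, member, weight_exponent)
  N <- length(member)
  S <- sum(member)
  null_es <- withr::with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) {
      mem <- logical(N)
      mem[sample.int(N, S)] <- TRUE
      .gsea_running_es(rl$stat, mem, weight_exponent)
    }, 0)
  })
  pval <- (1 + sum(abs(null_es) >= abs(es))) / (n_permutations + 1)
  same_sign <- null_es[sign(null_es) == sign(es)]
  nes <- if (length(same_sign)) es / mean(abs(same_sign)) else NA_real_
  structure(list(signature = sig$name, es = es, nes = nes, pval = pval,
                 size = S, n_permutations = n_permutations, seed = seed),
            class = "GSEAResult")
}

#' @export
print.GSEAResult <- function(x, ...) {
  cat(sprintf("GSEA '%s': ES = %.4f, NES = %.3f, p = %.4g (size %d, %d permutations)\n",
              x$signature, x$es, x$nes, x$pval, x$size, x$n_permutations))
  invisible(x)
}
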