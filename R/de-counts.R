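# Simplified count-based differential expression: median-of-ratios size
# factors, a per-gene negative-binomial Wald test between two conditions with
# method-of-moments dispersion, BH adjustment, DE-set extraction, and plain
# hypergeometric GO over-representation.
#
# This stage is deliberately minimal: no dispersion shrinkage across genes,
# no fold-change moderation, no independent filtering, and no
# transcript-length bias correction in the GO test. It is meant for
# simulation studies and as a transparent reference, not as a replacement for
# a production DE tool.

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over reference genes of the
#' ratio of that sample's count to the gene's geometric mean across samples.
#' Reference genes are those with positive counts in every sample (positive
#' geometric mean).
#'
#' @param counts Integer matrix, genes x samples (>= 2 samples).
#' @return Named numeric vector of positive size factors, one per sample.
#' @examples
#' size_factors(cbind(s1 = c(10, 20, 30), s2 = c(20, 40, 60)))
#' @export
size_factors <- function(counts) {
  counts <- .check_counts(counts)
  use <- rowSums(counts > 0) == ncol(counts)
  if (!any(use)) stop("no gene has positive counts in all samples")
  loggeo <- rowMeans(log(counts[use, , drop = FALSE]))
  sf <- apply(counts[use, , drop = FALSE], 2L,
              function(cnt) stats::median(exp(log(cnt) - loggeo)))
  sf
}

.check_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("need at least 2 samples")
  if (anyNA(counts) || any(counts < 0)) stop("counts must be non-negative")
  counts
}

#' Negative-binomial two-group Wald test per gene
#'
#' Counts are normalized by \code{\link{size_factors}}; the log2 fold change
#' is \code{log2((meanB + pseudo) / (meanA + pseudo))} on normalized means
#' (pseudo-count 0.5 normalized units stabilizes genes with a zero mean; such
#' genes are flagged). The per-gene dispersion is a method-of-moments
#' estimate pooled across the two conditions (floored at 1e-8), the standard
#' error of the log2 fold change follows from the NB variance function, and
#' the Wald statistic is referred to a t distribution with
#' \code{nA + nB - 2} degrees of freedom (a small-sample guard; the moment
#' dispersion estimate is noisy at typical replicate numbers). P-values are
#' BH-adjusted across all tested genes. Genes with zero counts in every
#' sample are dropped before testing.
#'
#' @param counts Integer matrix, genes x samples, with rownames as gene ids.
#' @param condition Factor/character vector of per-sample condition labels,
#'   aligned with \code{colnames(counts)}.
#' @param condA,condB The two condition labels to contrast (log2FC is B
#'   relative to A). Each needs >= 2 replicates.
#' @param pseudo Pseudo-count in normalized units (default 0.5).
#' @return Data frame: gene, baseMeanA, baseMeanB, log2FC, se, stat, pvalue,
#'   padj, zero_mean flag. Size factors are attached as attribute
#'   \code{"size_factors"}.
#' @export
nb_test <- function(counts, condition, condA, condB, pseudo = 0.5) {
  counts <- .check_counts(counts)
  if (length(condition) != ncol(counts))
    stop("condition must have one label per sample")
  sel_a <- which(condition == condA)
  sel_b <- which(condition == condB)
  if (length(sel_a) < 2L || length(sel_b) < 2L)
    stop("need at least 2 replicates per condition")
  sub <- counts[, c(sel_a, sel_b), drop = FALSE]
  keep <- rowSums(sub) > 0
  sub <- sub[keep, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no non-zero genes to test")

  sf <- size_factors(sub)
  norm <- sweep(sub, 2L, sf, "/")
  ia <- seq_along(sel_a)
  ib <- length(sel_a) + seq_along(sel_b)
  na <- length(ia); nb <- length(ib)

  mA <- rowMeans(norm[, ia, drop = FALSE])
  mB <- rowMeans(norm[, ib, drop = FALSE])
  vA <- apply(norm[, ia, drop = FALSE], 1L, stats::var)
  vB <- apply(norm[, ib, drop = FALSE], 1L, stats::var)

  # method-of-moments dispersion: Var(K/s) ~ q * mean(1/s) + alpha * q^2,
  # estimated per condition and pooled by residual df
  inv_a <- mean(1 / sf[ia]); inv_b <- mean(1 / sf[ib])
  alpha_a <- ifelse(mA > 0, (vA - mA * inv_a) / mA^2, 0)
  alpha_b <- ifelse(mB > 0, (vB - mB * inv_b) / mB^2, 0)
  wa <- ifelse(mA > 0, na - 1, 0); wb <- ifelse(mB > 0, nb - 1, 0)
  alpha <- pmax(1e-8, (wa * alpha_a + wb * alpha_b) / pmax(1, wa + wb))

  lfc <- log2((mB + pseudo) / (mA + pseudo))

  # delta-method variance of log2(mean + pseudo) under the NB model
  var_mA <- (mA * sum(1 / sf[ia]) + na * alpha * mA^2) / na^2
  var_mB <- (mB * sum(1 / sf[ib]) + nb * alpha * mB^2) / nb^2
  se <- sqrt(var_mA / (mA + pseudo)^2 + var_mB / (mB + pseudo)^2) / log(2)

  stat <- ifelse(se > 0, lfc / se, 0)
  df <- na + nb - 2
  pval <- 2 * stats::pt(-abs(stat), df)
  pval <- pmin(1, pval)

  res <- data.frame(
    gene = rownames(sub) %||% as.character(seq_len(nrow(sub))),
    baseMeanA = mA, baseMeanB = mB,
    log2FC = lfc, se = se, stat = stat,
    pvalue = pval, padj = bh_adjust(pval),
    zero_mean = mA == 0 | mB == 0,
    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "size_factors") <- sf
  attr(res, "contrast") <- c(A = condA, B = condB)
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract the differentially expressed gene set
#'
#' @param results \code{\link{nb_test}} result.
#' @param padj_threshold Adjusted-p cutoff (default 0.05).
#' @param fc_threshold Optional fold-change cutoff on the linear scale; genes
#'   must satisfy \code{|log2FC| > log2(fc_threshold)} to be retained.
#' @return List with \code{up} and \code{down} gene-id vectors (sign of
#'   log2FC) and the filtered \code{table}.
#' @export
de_set <- function(results, padj_threshold = 0.05, fc_threshold = NULL) {
  hit <- results$padj < padj_threshold
  if (!is.null(fc_threshold))
    hit <- hit & abs(results$log2FC) > log2(fc_threshold)
  tab <- results[hit & !is.na(hit), , drop = FALSE]
  list(up = tab$gene[tab$log2FC > 0],
       down = tab$gene[tab$log2FC < 0],
       table = tab)
}

#' Hypergeometric GO over-representation
#'
#' One-sided over-representation p per term: the upper hypergeometric tail of
#' the observed overlap between the DE set and the term's gene set within the
#' universe, BH-adjusted across terms. No transcript-length bias correction
#' is applied.
#'
#' @param de_genes Character vector of DE gene ids (must be a subset of
#'   \code{universe}).
#' @param universe All tested gene ids.
#' @param term_map Data frame with columns \code{term} and \code{gene};
#'   genes outside the universe are ignored.
#' @return Data frame: term, term_size, overlap, p, padj.
#' @export
go_overrep <- function(de_genes, universe, term_map) {
  if (!all(de_genes %in% universe)) stop("every DE gene must be in the universe")
  if (!all(c("term", "gene") %in% names(term_map)))
    stop("term_map needs columns term and gene")
  tm <- term_map[term_map$gene %in% universe, , drop = FALSE]
  sets <- split(unique.data.frame(tm)$gene, unique.data.frame(tm)$term)
  N <- length(unique(universe))
  n <- length(unique(de_genes))
  res <- do.call(rbind, lapply(names(sets), function(term) {
    K <- length(sets[[term]])
    x <- length(intersect(sets[[term]], de_genes))
    p <- stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, term_size = K, overlap = x, p = p,
               stringsAsFactors = FALSE)
  }))
  res$padj <- bh_adjust(res$p)
  res[order(res$p), , drop = FALSE]
}
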