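#' Median-of-ratios size factors
#'
#' The classic RNA-seq normalization: a per-gene geometric mean over samples
#' is the pseudo-reference (genes with any zero count are excluded from the
#' reference), and each sample's factor is the median of its count/reference
#' ratios.
#'
#' @param counts Genes x samples non-negative integer matrix.
#' @return Named numeric vector of positive per-sample size factors.
#' @export
size_factors <- function(counts) {
  stop_if_not_matrix(counts)
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) {
    stop("no gene has all-positive counts; size factors undefined", call. = FALSE)
  }
  logc <- log(counts[pos, , drop = FALSE])
  loggeo <- rowMeans(logc)
  apply(logc, 2, function(x) exp(median(x - loggeo)))
}

#' Log2 normalization of counts
#'
#' Divides each sample by its size factor and applies `log2(x + 1)`; the
#' scale used for variance ranking and network construction.
#'
#' @param counts Genes x samples matrix.
#' @param factors Positive per-sample size factors.
#' @return Genes x samples numeric matrix.
#' @export
normalize_log <- function(counts, factors = size_factors(counts)) {
  stop_if_not_matrix(counts)
  if (any(factors <= 0)) stop("size factors must be positive", call. = FALSE)
  log2(sweep(counts, 2, factors, "/") + 1)
}

#' PCA-based sample outlier screen
#'
#' PCA on the `n_top` most variable genes (samples as observations); a
#' sample is flagged when its PC1 or PC2 score deviates from the median by
#' more than `sd_cut` robust standard deviations (MAD-based). The robust
#' scale matters at typical cohort sizes: with an ordinary SD over n
#' samples no z-score can exceed `(n-1)/sqrt(n)` (about 2.85 at n = 10),
#' so a 3-SD rule could never fire there.
#'
#' @param normalized Log-normalized genes x samples matrix (>= 3 samples).
#' @param n_top Number of top-variance genes used (default 500).
#' @param sd_cut Flagging threshold in robust SDs (default 3).
#' @return Tibble: sample, pc1, pc2, outlier.
#' @export
pca_outlier_check <- function(normalized, n_top = 500L, sd_cut = 3) {
  stop_if_not_matrix(normalized)
  if (ncol(normalized) < 3) stop("need at least 3 samples", call. = FALSE)
  genes <- top_variable_genes(normalized, min(n_top, nrow(normalized)))
  pc <- prcomp(t(normalized[genes, , drop = FALSE]), center = TRUE, scale. = FALSE)
  s <- pc$x[, seq_len(min(2L, ncol(pc$x))), drop = FALSE]
  if (ncol(s) < 2) s <- cbind(s, 0)
  robust_flag <- function(x) {
    scale <- stats::mad(x)
    if (scale == 0) scale <- sd(x)
    if (scale == 0) return(rep(FALSE, length(x)))
    abs(x - median(x)) > sd_cut * scale
  }
  dev1 <- robust_flag(s[, 1])
  dev2 <- robust_flag(s[, 2])
  tibble::tibble(sample = colnames(normalized), pc1 = s[, 1], pc2 = s[, 2],
                 outlier = dev1 | dev2)
}

#' Negative-binomial Wald test for differential expression
#'
#' Per-gene two-group comparison on size-factor-normalized counts. The NB
#' dispersion is a method-of-moments estimate from the pooled within-group
#' variance, floored at 1e-8; the Wald statistic is the log fold change of
#' normalized group means over its delta-method standard error, referred to
#' the standard normal. All-zero genes are excluded. GS is `-log10(p)`.
#'
#' @param counts Genes x samples matrix.
#' @param metadata Tibble with columns `sample` and `group`; both groups
#'   need >= 2 samples.
#' @param ref Reference group level (log2FC is the other group vs `ref`).
#' @return Tibble: gene, base_mean, log2fc, p, gs.
#' @export
de_test <- function(counts, metadata, ref = "SR") {
  stop_if_not_matrix(counts)
  metadata <- metadata[match(colnames(counts), metadata$sample), ]
  if (anyNA(metadata$group)) stop("metadata does not cover all samples", call. = FALSE)
  grp <- metadata$group
  lv <- unique(grp)
  if (length(lv) != 2) stop("exactly two groups required", call. = FALSE)
  other <- setdiff(lv, ref)
  n1 <- sum(grp == ref); n2 <- sum(grp == other)
  if (n1 < 2 || n2 < 2) stop("both groups need at least 2 samples", call. = FALSE)

  norm <- sweep(counts, 2, size_factors(counts), "/")
  keep <- rowSums(counts) > 0
  norm <- norm[keep, , drop = FALSE]
  x1 <- norm[, grp == ref, drop = FALSE]
  x2 <- norm[, grp == other, drop = FALSE]
  mu1 <- rowMeans(x1) + 0.5   # pseudocount guards empty groups
  mu2 <- rowMeans(x2) + 0.5
  v1 <- apply(x1, 1, var)
  v2 <- apply(x2, 1, var)
  vp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  mu_bar <- (mu1 + mu2) / 2
  phi <- pmax((vp - mu_bar) / mu_bar^2, 1e-8)
  se <- sqrt((1 / mu1 + phi) / n1 + (1 / mu2 + phi) / n2)
  z <- log(mu2 / mu1) / se
  p <- 2 * pnorm(-abs(z))
  tibble::tibble(
    gene = rownames(norm),
    base_mean = rowMeans(norm),
    log2fc = log2(mu2 / mu1),
    p = p,
    gs = gene_significance(p)
  )
}

#' Gene significance
#'
#' `GS = -log10(p)`: the strength of a gene's differential-expression
#' evidence; GS > 2 corresponds to p < 0.01.
#'
#' @param p P-value(s) in (0, 1\]; zeros are capped at `max_gs` with a
#'   warning.
#' @param max_gs Cap applied at p = 0 (default 300).
#' @return Numeric GS value(s).
#' @export
gene_significance <- function(p, max_gs = 300) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  if (any(p == 0, na.rm = TRUE)) {
    warning("p-value of 0 capped at GS = ", max_gs, call. = FALSE)
  }
  pmin(-log10(p), max_gs)
}

#' Select the top-variance genes
#'
#' The `n` genes with the largest standard deviation across samples, ties
#' broken lexicographically by gene name; the standard pre-filter before
#' network construction.
#'
#' @param normalized Log-normalized genes x samples matrix with rownames.
#' @param n Number of genes to keep (<= number of genes).
#' @return Character vector of gene names, in decreasing-SD order.
#' @export
top_variable_genes <- function(normalized, n) {
  stop_if_not_matrix(normalized)
  if (n > nrow(normalized)) stop("`n` exceeds the number of genes", call. = FALSE)
  sds <- apply(normalized, 1, sd)
  ord <- order(-sds, rownames(normalized))
  rownames(normalized)[ord][seq_len(n)]
}
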