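#' Extend gene bounds strand-specifically
#'
#' Extends the 5' end of each gene upstream and the 3' end downstream before
#' SNP assignment, so regulatory SNPs just outside the transcript are
#' captured. For a "+" gene the 5' extension lowers `start`; for a "-" gene
#' it raises `end`. Coordinates are 1-based inclusive and floored at 1.
#'
#' @param annotation Tibble with columns gene, chrom, start, end, strand.
#' @param five_prime_bp,three_prime_bp Non-negative extensions in bp
#'   (defaults 2000 and 1000).
#' @return The annotation tibble with extended start/end.
#' @export
extend_gene_bounds <- function(annotation, five_prime_bp = 2000L,
                               three_prime_bp = 1000L) {
  if (five_prime_bp < 0 || three_prime_bp < 0) {
    stop("extensions must be non-negative", call. = FALSE)
  }
  annotation |>
    dplyr::mutate(
      up = ifelse(.data$strand == "+", five_prime_bp, three_prime_bp),
      down = ifelse(.data$strand == "+", three_prime_bp, five_prime_bp),
      start = pmax(1L, .data$start - .data$up),
      end = .data$end + .data$down
    ) |>
    dplyr::select(-"up", -"down")
}

#' Assign SNPs to genes by position
#'
#' A SNP belongs to every gene whose (extended) interval contains its
#' position, boundaries inclusive; SNPs under overlapping genes are counted
#' for each. Genes containing no SNP are absent from the result (and are
#' never scored).
#'
#' @param snps Tibble with columns chrom, pos, snp, p.
#' @param annotation (Extended) gene annotation tibble.
#' @return Tibble: gene, snp, p — one row per (gene, SNP) containment.
#' @export
assign_snps <- function(snps, annotation) {
  if (!all(grepl("^[A-Za-z0-9_.]+$", unique(snps$chrom)))) {
    stop("malformed chromosome labels in SNP table", call. = FALSE)
  }
  snps |>
    dplyr::inner_join(annotation, by = "chrom",
                      relationship = "many-to-many") |>
    dplyr::filter(.data$pos >= .data$start, .data$pos <= .data$end) |>
    dplyr::select("gene", "snp", "p")
}

#' Count LD proxy clusters among a gene's SNPs
#'
#' Builds the graph on the given SNPs with an edge wherever R2 strictly
#' exceeds `r2_threshold` and returns the number of connected components
#' (single-linkage transitive closure). Pairs absent from the LD table are
#' independent (R2 = 0). The count `k` is the effective number of
#' independent association signals the gene carries.
#'
#' @param snp_ids Character vector of SNP ids (non-empty).
#' @param ld Tibble with columns snp_a, snp_b, r2 (unordered pairs).
#' @param r2_threshold Strict lower bound for linkage (default 0.8).
#' @return Integer cluster count `k`.
#' @export
cluster_proxies <- function(snp_ids, ld, r2_threshold = 0.8) {
  if (length(snp_ids) == 0) stop("`snp_ids` is empty", call. = FALSE)
  if (r2_threshold <= 0 || r2_threshold >= 1) {
    stop("`r2_threshold` must lie in (0, 1)", call. = FALSE)
  }
  snp_ids <- unique(snp_ids)
  edges <- ld |>
    dplyr::filter(.data$r2 > r2_threshold,
                  .data$snp_a %in% snp_ids, .data$snp_b %in% snp_ids)
  g <- igraph::graph_from_data_frame(
    edges[, c("snp_a", "snp_b")], directed = FALSE,
    vertices = data.frame(name = snp_ids)
  )
  igraph::components(g)$no
}

#' LD-aware gene-level adjusted p-value
#'
#' Sidak correction of the gene's minimum SNP p-value over `k` effectively
#' independent proxy clusters: `p_adj = 1 - (1 - p_min)^k`. Longer or
#' denser genes accumulate more clusters and hence a stronger correction.
#'
#' @param p_values Non-empty numeric vector of SNP p-values in \[0, 1\].
#' @param k Proxy-cluster count (>= 1).
#' @return The adjusted gene p-value.
#' @export
gene_adjusted_p <- function(p_values, k) {
  if (length(p_values) == 0) stop("`p_values` is empty", call. = FALSE)
  if (k < 1) stop("`k` must be >= 1", call. = FALSE)
  p_min <- min(p_values)
  if (p_min < 0 || p_min > 1) stop("p-values must lie in [0, 1]", call. = FALSE)
  -expm1(k * log1p(-p_min))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR over a vector of p-values, order-preserving with the input.
#'
#' @param p Numeric vector of p-values.
#' @return Vector of q-values.
#' @export
bh_fdr <- function(p) {
  if (length(p) > 0 && (any(p < 0) || any(p > 1))) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p, method = "BH")
}

#' Score genes from GWAS summary statistics
#'
#' Full SNP-to-gene aggregation: extend gene bounds, assign SNPs by
#' position, count LD proxy clusters per gene, Sidak-adjust the minimum SNP
#' p-value over the cluster count, and attach Benjamini-Hochberg q-values
#' across all scored genes. Genes with `p_adj < alpha` are flagged; run once
#' on the discovery GWAS and once on the test GWAS to obtain the study-design
#' discovery/test gene sets.
#'
#' @param snps SNP tibble (chrom, pos, snp, p). Duplicate SNP ids keep the
#'   minimum p.
#' @param ld LD-pair tibble (snp_a, snp_b, r2).
#' @param annotation Gene annotation tibble (unextended).
#' @param r2_threshold Strict R2 threshold for proxy clustering.
#' @param five_prime_bp,three_prime_bp Gene-bound extensions in bp.
#' @param alpha Flagging threshold on `p_adj`.
#' @return Tibble: gene, n_snps, k, p_min, p_adj, q, flagged; sorted by
#'   `p_adj`.
#' @export
score_gwas_genes <- function(snps, ld, annotation, r2_threshold = 0.8,
                             five_prime_bp = 2000L, three_prime_bp = 1000L,
                             alpha = 0.05) {
  if (alpha <= 0 || alpha > 1) stop("`alpha` must lie in (0, 1]", call. = FALSE)
  snps <- snps |>
    dplyr::group_by(.data$chrom, .data$pos, .data$snp) |>
    dplyr::summarise(p = min(.data$p), .groups = "drop")
  ext <- extend_gene_bounds(annotation, five_prime_bp, three_prime_bp)
  assigned <- assign_snps(snps, ext)
  scores <- assigned |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      n_snps = dplyr::n_distinct(.data$snp),
      k = cluster_proxies(.data$snp, ld, r2_threshold),
      p_min = min(.data$p),
      .groups = "drop"
    ) |>
    dplyr::mutate(p_adj = purrr::map2_dbl(.data$p_min, .data$k,
                                          ~ gene_adjusted_p(.x, .y)),
                  q = bh_fdr(.data$p_adj),
                  flagged = .data$p_adj < alpha) |>
    dplyr::arrange(.data$p_adj, .data$gene)
  scores
}
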