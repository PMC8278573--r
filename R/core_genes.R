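#' Export the thresholded TOM edge list
#'
#' All unordered gene pairs within the selected modules whose topological
#' overlap strictly exceeds `cutoff`, in a Cytoscape-compatible layout
#' (fromNode < toNode lexicographically, no self edges, no duplicates).
#'
#' @param tom Symmetric TOM matrix with gene dimnames (e.g.
#'   `network$tom` from [build_network()]).
#' @param partition Tibble (gene, module).
#' @param modules Character vector of module names to export.
#' @param cutoff Strict edge-weight threshold (default 0.15).
#' @return Tibble: from_node, to_node, weight; sorted.
#' @export
export_edges <- function(tom, partition, modules, cutoff = 0.15) {
  unknown <- setdiff(modules, unique(partition$module))
  if (length(unknown) > 0) {
    stop("unknown module(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  genes <- sort(intersect(partition$gene[partition$module %in% modules],
                          rownames(tom)))
  if (length(genes) < 2) {
    return(tibble::tibble(from_node = character(), to_node = character(),
                          weight = numeric()))
  }
  sub <- tom[genes, genes, drop = FALSE]
  idx <- which(upper.tri(sub) & sub > cutoff, arr.ind = TRUE)
  tibble::tibble(from_node = genes[idx[, 1]], to_node = genes[idx[, 2]],
                 weight = sub[idx]) |>
    dplyr::arrange(.data$from_node, .data$to_node)
}

#' Genes crosslinked in the exported network
#'
#' Genes incident to at least one retained edge.
#'
#' @param edges Edge tibble from [export_edges()].
#' @return Sorted character vector of gene symbols.
#' @export
crosslinked_genes <- function(edges) {
  sort(unique(c(edges$from_node, edges$to_node)))
}

#' Select core genes
#'
#' A gene is core when it is crosslinked in the network, its GWAS-discovery
#' adjusted p-value is below `alpha`, and its gene significance exceeds
#' `gs_cut` (all comparisons strict). Genes absent from the discovery set
#' have a missing adjusted p and cannot be core.
#'
#' @param de DE tibble with columns `gene`, `gs` (and optionally `log2fc`).
#' @param crosslinked Character vector from [crosslinked_genes()].
#' @param discovery Gene-score tibble from [score_gwas_genes()] on the
#'   discovery GWAS (columns `gene`, `p_adj`).
#' @param gs_cut GS threshold (default 2, i.e. p < 0.01).
#' @param alpha Discovery adjusted-p threshold (default 0.05).
#' @return Tibble: gene, gs, p_dis, in_network, core.
#' @export
select_core_genes <- function(de, crosslinked, discovery, gs_cut = 2,
                              alpha = 0.05) {
  if (gs_cut < 0) stop("`gs_cut` must be >= 0", call. = FALSE)
  de |>
    dplyr::select("gene", "gs") |>
    dplyr::left_join(
      dplyr::select(discovery, "gene", p_dis = "p_adj"), by = "gene"
    ) |>
    dplyr::mutate(
      in_network = .data$gene %in% crosslinked,
      core = .data$in_network & !is.na(.data$p_dis) &
        .data$p_dis < alpha & .data$gs > gs_cut
    )
}

#' Confirm core genes against the GWAS test set
#'
#' A core gene is confirmed when its test-set adjusted p-value is below
#' `alpha`; core genes failing (or missing from) the test set are retained
#' with status "not_confirmed", everything else is "excluded".
#'
#' @param report Tibble from [select_core_genes()].
#' @param test Gene-score tibble from the test GWAS (columns `gene`,
#'   `p_adj`).
#' @param alpha Test adjusted-p threshold (default 0.05).
#' @return The report with added `p_test`, `confirmed`, `status`.
#' @export
confirm_with_test <- function(report, test, alpha = 0.05) {
  report |>
    dplyr::left_join(dplyr::select(test, "gene", p_test = "p_adj"),
                     by = "gene") |>
    dplyr::mutate(
      confirmed = .data$core & !is.na(.data$p_test) & .data$p_test < alpha,
      status = dplyr::case_when(
        .data$confirmed ~ "confirmed",
        .data$core ~ "not_confirmed",
        TRUE ~ "excluded"
      )
    )
}

#' Two-list gene overlap
#'
#' Exact Venn counts for two gene lists (e.g. the GS > 2 genes of the
#' trait-associated modules in each tissue).
#'
#' @param list_a,list_b Character vectors of gene symbols.
#' @return One-row tibble: a_only, b_only, both.
#' @export
overlap_gene_lists <- function(list_a, list_b) {
  a <- unique(list_a); b <- unique(list_b)
  tibble::tibble(a_only = length(setdiff(a, b)),
                 b_only = length(setdiff(b, a)),
                 both = length(intersect(a, b)))
}
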