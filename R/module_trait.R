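#' Dichotomize a module eigengene at its median
#'
#' Samples strictly above the median are "high"; samples at or below are
#' "low" (deterministic tie rule). The dichotomy is rank-based and hence
#' invariant to monotone transforms of the eigengene.
#'
#' @param me Numeric eigengene vector (>= 2 samples, non-constant).
#' @return Logical vector, `TRUE` = high.
#' @export
dichotomize_me <- function(me) {
  if (length(me) < 2) stop("need at least 2 samples", call. = FALSE)
  if (length(unique(me)) == 1) stop("constant eigengene", call. = FALSE)
  me > median(me)
}

#' Contingency coefficient of a dichotomized eigengene and a binary trait
#'
#' Pearson chi-square (no continuity correction) on the 2x2 table of
#' eigengene high/low against trait, with `CC = sqrt(chi2 / (chi2 + n))`.
#' For a 2x2 table CC is at most `sqrt(1/2) ~ 0.707`, attained at perfect
#' balanced separation. A zero margin yields CC = 0 with a warning.
#'
#' @param binary_me Logical (or two-level) vector from [dichotomize_me()].
#' @param trait Two-level vector of the same length (e.g. AF/SR).
#' @return One-row tibble: n11, n12, n21, n22, chi2, cc, p, n.
#' @export
contingency_coefficient <- function(binary_me, trait) {
  if (length(binary_me) != length(trait)) {
    stop("vectors must have equal length", call. = FALSE)
  }
  f1 <- factor(binary_me)
  f2 <- factor(trait)
  if (nlevels(f1) > 2 || nlevels(f2) > 2) {
    stop("both variables must be binary", call. = FALSE)
  }
  tab <- table(f1, f2)
  n <- sum(tab)
  if (any(dim(tab) < 2) || any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("zero margin: contingency coefficient reported as 0", call. = FALSE)
    chi2 <- 0; p <- 1
    tab2 <- matrix(0, 2, 2)
    tab2[seq_len(nrow(tab)), seq_len(ncol(tab))] <- tab
    tab <- tab2
  } else {
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    chi2 <- unname(ct$statistic)
    p <- unname(ct$p.value)
  }
  tibble::tibble(n11 = tab[1, 1], n12 = tab[1, 2], n21 = tab[2, 1],
                 n22 = tab[2, 2], chi2 = chi2,
                 cc = sqrt(chi2 / (chi2 + n)), p = p, n = n)
}

#' Module-trait association via the contingency coefficient
#'
#' Scores every module eigengene against a binary trait: the eigengene is
#' dichotomized at its median and crossed with the trait in a 2x2 table.
#'
#' @param eigengenes An `eigengene_set` from [module_eigengenes()].
#' @param metadata Tibble with columns `sample` and the trait column.
#' @param trait_col Name of the trait column (default "group").
#' @return Tibble: module, table cells, chi2, cc, p, n.
#' @export
module_trait_cc <- function(eigengenes, metadata, trait_col = "group") {
  me <- eigengenes$me
  metadata <- metadata[match(rownames(me), metadata$sample), ]
  if (anyNA(metadata$sample)) stop("metadata does not cover all samples", call. = FALSE)
  purrr::map_dfr(colnames(me), function(m) {
    dplyr::bind_cols(
      tibble::tibble(module = m),
      contingency_coefficient(dichotomize_me(me[, m]), metadata[[trait_col]])
    )
  })
}

#' Module membership
#'
#' Pearson correlation of every gene's expression with every module
#' eigengene. A gene's MM to its own module measures how central it is to
#' the module; constant genes get `NA`.
#'
#' @param expr Genes x samples matrix.
#' @param eigengenes An `eigengene_set` on the same samples.
#' @return Tibble: gene, module, mm.
#' @export
module_membership <- function(expr, eigengenes) {
  stop_if_not_matrix(expr)
  me <- eigengenes$me
  if (nrow(me) != ncol(expr)) {
    stop("eigengenes and expression cover different samples", call. = FALSE)
  }
  sds <- apply(expr, 1, sd)
  mm <- suppressWarnings(cor(t(expr), me))
  mm[sds == 0, ] <- NA_real_
  tibble::as_tibble(mm, rownames = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "module", values_to = "mm")
}

#' Association between gene significance and module membership
#'
#' For each module, the Pearson correlation R (with its t-test p-value)
#' between a gene's membership in the module and its differential-expression
#' gene significance, over the module's own genes. A module is flagged
#' trait-relevant when `p < p_cut` and `R > r_cut`.
#'
#' @param mm Module-membership tibble from [module_membership()].
#' @param de DE tibble with columns `gene` and `gs`.
#' @param partition Tibble (gene, module).
#' @param p_cut,r_cut Significance thresholds (defaults 0.05 and 0.3).
#' @return Tibble: module, n_genes, r, p, significant.
#' @export
gs_mm_association <- function(mm, de, partition, p_cut = 0.05, r_cut = 0.3) {
  mods <- sort(setdiff(unique(partition$module), "grey"))
  purrr::map_dfr(mods, function(m) {
    genes <- partition$gene[partition$module == m]
    dat <- mm |>
      dplyr::filter(.data$module == m, .data$gene %in% genes) |>
      dplyr::inner_join(de[, c("gene", "gs")], by = "gene") |>
      dplyr::filter(!is.na(.data$mm))
    if (nrow(dat) < 3) {
      return(tibble::tibble(module = m, n_genes = nrow(dat), r = NA_real_,
                            p = NA_real_, significant = FALSE))
    }
    ct <- cor.test(dat$mm, dat$gs, method = "pearson")
    tibble::tibble(module = m, n_genes = nrow(dat),
                   r = unname(ct$estimate), p = ct$p.value,
                   significant = ct$p.value < p_cut & unname(ct$estimate) > r_cut)
  })
}
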