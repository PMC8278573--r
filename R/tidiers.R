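#' Tidy a coexpression network
#'
#' One row per gene with its module assignment and, when eigengenes are
#' available, the gene's membership (correlation with its own module's
#' eigengene).
#'
#' @param x A `coex_network` from [build_network()].
#' @param ... Unused.
#' @return Tibble: gene, module, mm.
#' @exportS3Method generics::tidy
tidy.coex_network <- function(x, ...) {
  out <- x$partition
  out$mm <- NA_real_
  if (!is.null(x$eigengenes)) {
    mm <- module_membership(x$expr, x$eigengenes)
    own <- dplyr::semi_join(mm, out, by = c("gene", "module"))
    out <- out |>
      dplyr::select(-"mm") |>
      dplyr::left_join(own, by = c("gene", "module"))
  }
  out
}

#' Glance at a coexpression network
#'
#' @param x A `coex_network`.
#' @param ... Unused.
#' @return One-row tibble: n_genes, power, fit_r2, n_modules, n_grey,
#'   largest_module.
#' @exportS3Method generics::glance
glance.coex_network <- function(x, ...) {
  sizes <- table(x$partition$module[x$partition$module != "grey"])
  if (length(sizes) > 0) {
    # ties in size resolve to the canonical colour order
    ord <- order(match(names(sizes), module_colors(length(sizes) + 10)))
    sizes <- sizes[ord]
  }
  fit <- NA_real_
  if (!is.null(x$soft_threshold)) {
    rep <- x$soft_threshold$report
    fit <- rep$fit_r2[rep$power == x$power]
  }
  tibble::tibble(
    n_genes = length(x$genes), power = x$power, fit_r2 = fit,
    n_modules = length(sizes),
    n_grey = sum(x$partition$module == "grey"),
    largest_module = if (length(sizes) > 0) names(sizes)[which.max(sizes)] else NA_character_
  )
}

#' Tidy an eigengene set
#'
#' @param x An `eigengene_set` from [module_eigengenes()].
#' @param ... Unused.
#' @return Tibble: module, sample, me, var_explained.
#' @exportS3Method generics::tidy
tidy.eigengene_set <- function(x, ...) {
  tibble::as_tibble(x$me, rownames = "sample") |>
    tidyr::pivot_longer(-"sample", names_to = "module", values_to = "me") |>
    dplyr::left_join(
      tibble::tibble(module = names(x$var_explained),
                     var_explained = unname(x$var_explained)),
      by = "module") |>
    dplyr::arrange(.data$module, .data$sample)
}

#' Tidy a soft-threshold report
#'
#' @param x A `soft_threshold` from [pick_soft_threshold()].
#' @param ... Unused.
#' @return The report tibble with a `chosen` flag column.
#' @exportS3Method generics::tidy
tidy.soft_threshold <- function(x, ...) {
  dplyr::mutate(x$report, chosen = .data$power == x$power)
}
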