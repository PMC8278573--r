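#' Plot the soft-threshold search
#'
#' Scale-free fit and mean connectivity against candidate powers, the
#' standard two-panel diagnostic condensed to one faceted figure.
#'
#' @param object A `soft_threshold` from [pick_soft_threshold()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.soft_threshold <- function(object, ...) {
  dat <- tidy(object) |>
    tidyr::pivot_longer(c("fit_r2", "k_mean"), names_to = "panel") |>
    dplyr::mutate(panel = dplyr::recode(.data$panel,
                                        fit_r2 = "signed scale-free fit R²",
                                        k_mean = "mean connectivity"))
  ggplot2::ggplot(dat, ggplot2::aes(.data$power, .data$value)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_text(ggplot2::aes(label = .data$power,
                                    colour = .data$chosen), size = 3) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black", `TRUE` = "red"),
                                 guide = "none") +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "soft-threshold power", y = NULL)
}

#' Plot module-trait contingency coefficients
#'
#' @param module_trait Tibble from [module_trait_cc()].
#' @param p_cut Significance threshold highlighted (default 0.05).
#' @return A ggplot object.
#' @export
plot_module_trait <- function(module_trait, p_cut = 0.05) {
  dat <- dplyr::mutate(module_trait,
                       significant = .data$p < p_cut,
                       module = stats::reorder(.data$module, .data$cc))
  ggplot2::ggplot(dat, ggplot2::aes(.data$cc, .data$module,
                                    fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("p = %.3g", .data$p)),
                       hjust = -0.05, size = 3) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70", `TRUE` = "firebrick")) +
    ggplot2::xlim(0, sqrt(0.5) * 1.3) +
    ggplot2::labs(x = "contingency coefficient", y = NULL,
                  fill = sprintf("p < %.2g", p_cut))
}

#' Plot a GSEA running enrichment sum
#'
#' @param ranked Ranked tibble (gene, score).
#' @param set Gene set (character vector).
#' @param weight Hit-weight exponent (default 1).
#' @return A ggplot object.
#' @export
plot_running_enrichment <- function(ranked, set, weight = 1) {
  run <- running_enrichment(ranked, set, weight)
  ggplot2::ggplot(run$running, ggplot2::aes(.data$position, .data$running)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line(colour = "darkgreen") +
    ggplot2::geom_rug(data = dplyr::filter(run$running, .data$hit),
                      sides = "b", length = ggplot2::unit(0.03, "npc")) +
    ggplot2::labs(x = "rank in ordered gene list",
                  y = "running enrichment score",
                  title = sprintf("ES = %.3f", run$es))
}

#' Plot gene-significance versus module-membership for one module
#'
#' @param mm Module-membership tibble from [module_membership()].
#' @param de DE tibble with `gene` and `gs`.
#' @param partition Partition tibble (gene, module).
#' @param module Module name.
#' @return A ggplot object.
#' @export
plot_gs_mm <- function(mm, de, partition, module) {
  genes <- partition$gene[partition$module == module]
  dat <- mm |>
    dplyr::filter(.data$module == !!module, .data$gene %in% genes) |>
    dplyr::inner_join(de[, c("gene", "gs")], by = "gene")
  ggplot2::ggplot(dat, ggplot2::aes(.data$mm, .data$gs)) +
    ggplot2::geom_point(colour = module, alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "black", linewidth = 0.4) +
    ggplot2::labs(x = sprintf("module membership (%s)", module),
                  y = "gene significance")
}
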