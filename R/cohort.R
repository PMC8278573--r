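#' Fisher exact odds ratio for a 2x2 table
#'
#' Conditional maximum-likelihood odds ratio under the noncentral
#' hypergeometric model, the two-sided Fisher exact p-value (sum of table
#' probabilities at or below the observed), and the exact conditional 95%
#' confidence interval. The sample cross-product estimate `ad/bc` is
#' reported alongside.
#'
#' @param tab 2x2 matrix of non-negative integer counts, rows = outcome,
#'   columns = group (or any orientation; the OR is orientation-consistent).
#' @param conf_level Confidence level (default 0.95).
#' @return One-row tibble: or (conditional MLE), or_cross, p, ci_lo, ci_hi.
#' @export
fisher_or <- function(tab, conf_level = 0.95) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2)) || any(tab < 0)) {
    stop("`tab` must be a non-negative 2x2 matrix", call. = FALSE)
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("zero margin: odds ratio undefined", call. = FALSE)
    return(tibble::tibble(or = NA_real_, or_cross = NA_real_, p = NA_real_,
                          ci_lo = NA_real_, ci_hi = NA_real_))
  }
  ft <- fisher.test(tab, conf.level = conf_level)
  tibble::tibble(
    or = unname(ft$estimate),
    or_cross = (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1]),
    p = ft$p.value,
    ci_lo = ft$conf.int[1],
    ci_hi = ft$conf.int[2]
  )
}

#' Welch confidence interval for a mean difference
#'
#' Two-sample interval for `mean2 - mean1` from summary statistics using
#' the Welch-Satterthwaite (unpooled) degrees of freedom, with the
#' corresponding two-sided t p-value.
#'
#' @param mean1,sd1,n1 Group 1 summary statistics (n1 >= 2, sd1 > 0).
#' @param mean2,sd2,n2 Group 2 summary statistics.
#' @param conf_level Confidence level (default 0.95).
#' @return One-row tibble: diff, ci_lo, ci_hi, df, p.
#' @export
welch_interval <- function(mean1, sd1, n1, mean2, sd2, n2,
                           conf_level = 0.95) {
  if (n1 < 2 || n2 < 2) stop("both groups need n >= 2", call. = FALSE)
  if (sd1 <= 0 || sd2 <= 0) stop("standard deviations must be positive", call. = FALSE)
  v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
  se <- sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  diff <- mean2 - mean1
  tq <- qt(1 - (1 - conf_level) / 2, df)
  tibble::tibble(diff = diff, ci_lo = diff - tq * se, ci_hi = diff + tq * se,
                 df = df, p = 2 * pt(-abs(diff / se), df))
}

#' Mann-Whitney U test
#'
#' Exact null distribution when the combined sample size is at most 20 and
#' there are no ties; otherwise the normal approximation with continuity
#' and tie correction.
#'
#' @param x,y Numeric vectors (each non-empty).
#' @return One-row tibble: u, p (two-sided).
#' @export
mann_whitney <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) {
    stop("both groups need at least one value", call. = FALSE)
  }
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y)) <= 20 && !ties
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  tibble::tibble(u = unname(wt$statistic), p = wt$p.value)
}

#' qPCR relative expression by the delta-delta-Ct method
#'
#' Per sample, `dCt = Ct_target - Ct_reference`; per gene,
#' `ddCt = mean dCt(case) - mean dCt(control)` and relative expression
#' `2^-ddCt`. Group differences in dCt are tested with the Mann-Whitney U
#' test. Samples missing a reference Ct are dropped with a warning.
#'
#' @param records Tibble with columns `sample`, `group`, `gene`,
#'   `ct_target`, `ct_reference`.
#' @param case,control Group labels (defaults "AF" and "SR").
#' @return Tibble: gene, n_case, n_control, ddct, fold_change, u, p.
#' @export
ddct_fold_change <- function(records, case = "AF", control = "SR") {
  miss <- is.na(records$ct_reference) | is.na(records$ct_target)
  if (any(miss)) {
    warning(sum(miss), " sample record(s) without Ct dropped", call. = FALSE)
    records <- records[!miss, , drop = FALSE]
  }
  records |>
    dplyr::mutate(dct = .data$ct_target - .data$ct_reference) |>
    dplyr::group_by(.data$gene) |>
    dplyr::group_modify(function(d, key) {
      dcase <- d$dct[d$group == case]
      dctrl <- d$dct[d$group == control]
      if (length(dcase) == 0 || length(dctrl) == 0) {
        stop("both groups must be non-empty for gene ", key$gene, call. = FALSE)
      }
      ddct <- mean(dcase) - mean(dctrl)
      mw <- mann_whitney(dcase, dctrl)
      tibble::tibble(n_case = length(dcase), n_control = length(dctrl),
                     ddct = ddct, fold_change = 2^(-ddct),
                     u = mw$u, p = mw$p)
    }) |>
    dplyr::ungroup()
}

#' Per-sample qPCR relative expression
#'
#' `2^-(dCt - mean dCt(control))` per sample, the per-sample companion of
#' [ddct_fold_change()].
#'
#' @inheritParams ddct_fold_change
#' @return Tibble: sample, group, gene, dct, rel_expr.
#' @export
ddct_per_sample <- function(records, control = "SR") {
  records |>
    dplyr::mutate(dct = .data$ct_target - .data$ct_reference) |>
    dplyr::group_by(.data$gene) |>
    dplyr::mutate(rel_expr = 2^(-(.data$dct - mean(.data$dct[.data$group == control])))) |>
    dplyr::ungroup() |>
    dplyr::select("sample", "group", "gene", "dct", "rel_expr")
}
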