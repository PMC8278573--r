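#' Read a GMT gene-set file
#'
#' Standard tab-separated format: set name, description, then member genes.
#'
#' @param path Path to a .gmt file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1)
  if (anyDuplicated(names(sets))) stop("duplicate set names in GMT", call. = FALSE)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Description field (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description, sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

# Sort a ranked tibble (gene, score) descending by score, ties broken
# lexicographically by gene for determinism.
rank_order <- function(ranked) {
  ranked[order(-ranked$score, ranked$gene), , drop = FALSE]
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked gene list accumulating `|score|^weight` (normalized to
#' sum 1 over the set's hits) at each set member and subtracting
#' `1 / (N - n_hits)` at each miss; the enrichment score is the running
#' sum's maximum deviation from zero, signed. `weight = 0` reduces to the
#' classical KS statistic on ranks.
#'
#' @param ranked Tibble with columns `gene` and `score`; sorted internally
#'   by decreasing score with lexicographic tie-break.
#' @param set Character vector of gene symbols; must intersect the list.
#' @param weight Hit-weight exponent (default 1).
#' @return The ES (numeric scalar in \[-1, 1\]).
#' @export
enrichment_score <- function(ranked, set, weight = 1) {
  running_enrichment(ranked, set, weight)$es
}

#' Running enrichment sum
#'
#' The per-position running sum behind [enrichment_score()], for plotting.
#'
#' @inheritParams enrichment_score
#' @return List with `es` and `running` (tibble: position, gene, hit,
#'   running).
#' @export
running_enrichment <- function(ranked, set, weight = 1) {
  ranked <- rank_order(ranked)
  hit <- ranked$gene %in% set
  if (!any(hit)) stop("gene set is disjoint from the ranked list", call. = FALSE)
  n <- nrow(ranked)
  nh <- sum(hit)
  if (nh == n) stop("gene set covers the entire ranked list", call. = FALSE)
  w <- abs(ranked$score)^weight
  w[!hit] <- 0
  if (sum(w) == 0) w[hit] <- 1   # degenerate all-zero scores: unweighted
  inc <- ifelse(hit, w / sum(w), -1 / (n - nh))
  run <- cumsum(inc)
  es <- run[which.max(abs(run))]
  list(es = es,
       running = tibble::tibble(position = seq_len(n), gene = ranked$gene,
                                hit = hit, running = run))
}

#' Gene-set permutation null for the enrichment score
#'
#' ES values of `n_perm` random gene sets of a given size drawn without
#' replacement from the ranked list; the null used for nominal p-values,
#' normalization and FDR.
#'
#' @inheritParams enrichment_score
#' @param set_size Size of the random sets.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed; the draw is reproducible.
#' @return Numeric vector of null ES values.
#' @export
permutation_null <- function(ranked, set_size, n_perm = 1000L, seed = 1L,
                             weight = 1) {
  if (n_perm < 100) stop("`n_perm` must be >= 100", call. = FALSE)
  if (set_size > nrow(ranked)) {
    stop("`set_size` exceeds the ranked-list length", call. = FALSE)
  }
  ranked <- rank_order(ranked)
  with_seed(substream_seed(seed, paste0("gsea_null_", set_size)), {
    vapply(seq_len(n_perm), function(i) {
      enrichment_score(ranked, sample(ranked$gene, set_size), weight)
    }, numeric(1))
  })
}

#' Gene-set enrichment analysis with a gene-set permutation null
#'
#' Computes the weighted-KS enrichment score of every set against the
#' ranked list, a permutation null per distinct set size, sign-matched
#' nominal p-values, normalized enrichment scores
#' (`NES = ES / mean(|null ES| of the same sign)`), and the standard
#' positive/negative tail-ratio FDR q-values. Sets with `q < fdr_cut` are
#' flagged.
#'
#' @param ranked Tibble with columns `gene` and `score` (e.g.
#'   `sign(log2fc) * gs` from the DE test).
#' @param sets Named list of gene sets (e.g. from [read_gmt()]).
#' @param n_perm Permutations per set size (default 1000).
#' @param weight Hit-weight exponent (default 1).
#' @param seed Integer seed for the permutation draws.
#' @param min_size,max_size Bounds on the set/list overlap (defaults 15 and
#'   500); sets outside are dropped.
#' @param fdr_cut Flagging threshold on q (default 0.25).
#' @return Tibble: set, size, es, nes, p, q, flagged; sorted by p.
#' @export
gsea <- function(ranked, sets, n_perm = 1000L, weight = 1, seed = 1L,
                 min_size = 15L, max_size = 500L, fdr_cut = 0.25) {
  ranked <- rank_order(ranked)
  sizes <- vapply(sets, function(s) sum(ranked$gene %in% s), integer(1))
  keep <- sizes >= min_size & sizes <= max_size
  if (!any(keep)) stop("no gene set within the size bounds", call. = FALSE)
  sets <- sets[keep]; sizes <- sizes[keep]

  nulls <- lapply(sort(unique(sizes)), function(sz) {
    permutation_null(ranked, sz, n_perm, seed, weight)
  })
  names(nulls) <- as.character(sort(unique(sizes)))

  res <- purrr::map_dfr(seq_along(sets), function(i) {
    es <- enrichment_score(ranked, sets[[i]], weight)
    null <- nulls[[as.character(sizes[i])]]
    same <- if (es >= 0) null[null >= 0] else null[null < 0]
    p <- if (length(same) == 0) NA_real_ else {
      (sum(abs(same) >= abs(es)) + 1) / (length(same) + 1)
    }
    nes <- if (length(same) == 0) NA_real_ else es / mean(abs(same))
    tibble::tibble(set = names(sets)[i], size = sizes[i], es = es,
                   nes = nes, p = p)
  })

  # Pooled null NES per sign for the tail-ratio FDR.
  null_nes <- unlist(lapply(nulls, function(null) {
    pos <- null[null >= 0]; neg <- null[null < 0]
    c(if (length(pos) > 0) pos / mean(pos) else numeric(0),
      if (length(neg) > 0) -(neg / mean(-neg)) else numeric(0))
  }), use.names = FALSE)
  res$q <- vapply(res$nes, function(nes) {
    if (is.na(nes)) return(NA_real_)
    if (nes >= 0) {
      num <- mean(null_nes[null_nes >= 0] >= nes)
      den <- mean(res$nes[!is.na(res$nes) & res$nes >= 0] >= nes)
    } else {
      num <- mean(null_nes[null_nes < 0] <= nes)
      den <- mean(res$nes[!is.na(res$nes) & res$nes < 0] <= nes)
    }
    min(1, max(0, num / max(den, .Machine$double.eps)))
  }, numeric(1))
  res$flagged <- !is.na(res$q) & res$q < fdr_cut
  dplyr::arrange(res, .data$p, .data$set)
}
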