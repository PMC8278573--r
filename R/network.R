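#' Weighted coexpression adjacency
#'
#' Raises the gene-gene Pearson correlation to the soft-threshold power:
#' unsigned `|cor|^beta`, or signed `((1 + cor) / 2)^beta`. The diagonal is
#' set to 1 but excluded from all connectivity sums downstream.
#'
#' @param expr Genes x samples numeric matrix (>= 3 samples, complete, no
#'   zero-variance gene).
#' @param power Soft-threshold exponent beta (>= 1).
#' @param mode "unsigned" (default) or "signed".
#' @return Symmetric adjacency matrix with entries in \[0, 1\].
#' @export
wgcna_adjacency <- function(expr, power, mode = c("unsigned", "signed")) {
  mode <- match.arg(mode)
  stop_if_not_matrix(expr)
  if (power < 1) stop("`power` must be >= 1", call. = FALSE)
  if (ncol(expr) < 3) stop("need at least 3 samples", call. = FALSE)
  sds <- apply(expr, 1, sd)
  if (any(sds == 0)) {
    stop("zero-variance gene(s): ",
         paste(head(rownames(expr)[sds == 0], 5), collapse = ", "),
         call. = FALSE)
  }
  cc <- cor(t(expr))
  a <- if (mode == "unsigned") abs(cc)^power else ((1 + cc) / 2)^power
  diag(a) <- 1
  a
}

#' Scale-free soft-threshold selection
#'
#' For each candidate power, computes the connectivity distribution and the
#' signed scale-free model fit: the R-squared of `log10 p(k)` on `log10 k`
#' over 10 equal-width connectivity bins, signed by the regression slope.
#' The chosen power is the smallest whose signed fit reaches `r2_target`
#' (default 0.85), falling back to the best-fitting power.
#'
#' @param expr Genes x samples matrix.
#' @param powers Candidate powers (default 1:20).
#' @param r2_target Fit threshold for acceptance.
#' @param mode Network type passed to [wgcna_adjacency()].
#' @return A `soft_threshold` object: list with `report` (tibble: power,
#'   fit_r2, k_mean, k_median, k_max) and `power` (the choice).
#' @export
pick_soft_threshold <- function(expr, powers = 1:20, r2_target = 0.85,
                                mode = "unsigned") {
  if (length(powers) == 0) stop("`powers` is empty", call. = FALSE)
  cc <- cor(t(expr))
  base <- if (mode == "unsigned") abs(cc) else (1 + cc) / 2
  diag(base) <- 0
  rows <- lapply(powers, function(b) {
    k <- rowSums(base^b)
    tibble::tibble(power = b, fit_r2 = scale_free_fit(k),
                   k_mean = mean(k), k_median = median(k), k_max = max(k))
  })
  report <- dplyr::bind_rows(rows)
  ok <- which(!is.na(report$fit_r2) & report$fit_r2 >= r2_target)
  chosen <- if (length(ok) > 0) {
    report$power[ok[1]]
  } else {
    report$power[which.max(report$fit_r2)]
  }
  structure(list(report = report, power = chosen), class = "soft_threshold")
}

# Signed scale-free topology fit R^2 from a connectivity vector, using 10
# equal-width bins of k; NA when fewer than 3 usable bins.
scale_free_fit <- function(k, n_bins = 10L) {
  k <- k[k > 0]
  if (length(k) < 3) return(NA_real_)
  br <- seq(min(k), max(k), length.out = n_bins + 1L)
  bin <- cut(k, breaks = br, include.lowest = TRUE)
  cnt <- tapply(k, bin, length)
  kb <- tapply(k, bin, mean)
  use <- !is.na(cnt) & cnt > 0 & kb > 0
  if (sum(use) < 3) return(NA_real_)
  x <- log10(kb[use])
  y <- log10(cnt[use] / length(k))
  fit <- stats::lm(y ~ x)
  # scale-free topology implies a *negative* slope of log p(k) on log k, so
  # the signed fit is -sign(slope) * R^2 (positive when the fit is scale-free)
  unname(-summary(fit)$r.squared * sign(stats::coef(fit)[2]))
}

#' Topological overlap matrix
#'
#' Neighborhood-sharing similarity of the weighted network:
#' `TOM_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `L_ij = sum_u a_iu a_uj` (u != i, j) and connectivity `k_i` excluding
#' the diagonal; `TOM_ii = 1`.
#'
#' @param adjacency Symmetric matrix with entries in \[0, 1\].
#' @return Symmetric TOM matrix in \[0, 1\].
#' @export
tom_similarity <- function(adjacency) {
  stop_if_not_matrix(adjacency)
  if (!isSymmetric(unname(adjacency), tol = 1e-10)) {
    stop("adjacency must be symmetric", call. = FALSE)
  }
  a <- adjacency
  diag(a) <- 0
  l <- a %*% a
  k <- rowSums(a)
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (l + a) / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' Average-linkage gene tree
#'
#' Agglomerative clustering of the TOM dissimilarity `1 - TOM`.
#'
#' @param dissimilarity Symmetric matrix with zero diagonal, no NaN.
#' @return An [stats::hclust] tree.
#' @export
cluster_gene_tree <- function(dissimilarity) {
  stop_if_not_matrix(dissimilarity)
  if (anyNA(dissimilarity)) stop("dissimilarity contains NA/NaN", call. = FALSE)
  if (any(abs(diag(dissimilarity)) > 1e-12)) {
    stop("dissimilarity diagonal must be zero", call. = FALSE)
  }
  tree <- hclust(as.dist(dissimilarity), method = "average")
  # average linkage is monotone; exact ties can still produce epsilon-scale
  # height inversions in floating point, which cutree() refuses
  if (is.unsorted(tree$height)) {
    fixed <- cummax(tree$height)
    if (max(fixed - tree$height) > 1e-8) {
      stop("non-monotone merge heights", call. = FALSE)
    }
    tree$height <- fixed
  }
  tree
}

#' Static tree cut into modules
#'
#' Cuts the gene tree at `cut_quantile` of its maximum merge height;
#' clusters smaller than `min_module_size` become background ("grey").
#' Surviving clusters are named by decreasing size with the canonical
#' colour order (turquoise, blue, brown, ...), ties broken by the
#' lexicographically smallest member gene.
#'
#' @param tree An [stats::hclust] tree with gene labels.
#' @param min_module_size Minimum module size (default 30).
#' @param cut_quantile Fraction of the maximum merge height at which to cut
#'   (default 0.99).
#' @return Tibble: gene, module.
#' @export
cut_gene_tree <- function(tree, min_module_size = 30L, cut_quantile = 0.99) {
  if (min_module_size < 2) stop("`min_module_size` must be >= 2", call. = FALSE)
  cl <- cutree(tree, h = cut_quantile * max(tree$height))
  tb <- tibble::tibble(gene = names(cl), cluster = unname(cl))
  info <- tb |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(size = dplyr::n(), first_gene = min(.data$gene),
                     .groups = "drop") |>
    dplyr::filter(.data$size >= min_module_size) |>
    dplyr::arrange(dplyr::desc(.data$size), .data$first_gene)
  info$module <- module_colors(nrow(info))
  tb |>
    dplyr::left_join(info[, c("cluster", "module")], by = "cluster") |>
    dplyr::mutate(module = dplyr::coalesce(.data$module, "grey")) |>
    dplyr::select("gene", "module")
}

#' Module eigengenes
#'
#' The first principal component of each module's standardized expression:
#' genes are scaled to zero mean and unit variance over samples, the module
#' eigengene (ME) is the first right-singular vector across samples,
#' sign-oriented so that it correlates non-negatively with the module's
#' mean standardized expression. Variance explained is the first squared
#' singular value over the total.
#'
#' @param expr Genes x samples matrix covering all module genes.
#' @param partition Tibble (gene, module); "grey" is skipped.
#' @return An `eigengene_set`: list with `me` (samples x modules matrix)
#'   and `var_explained` (named vector).
#' @export
module_eigengenes <- function(expr, partition) {
  stop_if_not_matrix(expr)
  mods <- sort(unique(partition$module[partition$module != "grey"]))
  if (length(mods) == 0) stop("no non-grey module in partition", call. = FALSE)
  me <- matrix(NA_real_, nrow = ncol(expr), ncol = length(mods),
               dimnames = list(colnames(expr), mods))
  ve <- setNames(numeric(length(mods)), mods)
  for (m in mods) {
    genes <- partition$gene[partition$module == m]
    if (length(genes) < 2) stop("module '", m, "' has fewer than 2 genes", call. = FALSE)
    x <- expr[genes, , drop = FALSE]
    sds <- apply(x, 1, sd)
    if (any(sds == 0)) {
      stop("constant gene(s) in module '", m, "'", call. = FALSE)
    }
    xs <- t(scale(t(x)))
    sv <- svd(xs)
    v1 <- sv$v[, 1]
    if (cor(v1, colMeans(xs)) < 0) v1 <- -v1
    me[, m] <- v1
    ve[m] <- sv$d[1]^2 / sum(sv$d^2)
  }
  structure(list(me = me, var_explained = ve), class = "eigengene_set")
}

# Cut a subtree at the height that maximizes the number of clusters of at
# least `min_size` genes (ties resolved toward the larger height, i.e. the
# most stable such cut). Returns the cutree labels.
adaptive_height_cut <- function(d_sub, min_size) {
  tr <- cluster_gene_tree(d_sub)
  hs <- sort(unique(tr$height))
  mids <- c((hs[-1] + hs[-length(hs)]) / 2, max(hs) * 1.001)
  best <- NULL
  best_n <- -1L
  for (h in mids) {
    cl <- cutree(tr, h = h)
    n <- sum(table(cl) >= min_size)
    if (n >= best_n) { best_n <- n; best <- cl }
  }
  best
}

# Recursively split a branch: apply the adaptive cut, recurse into every
# cluster of >= min_size genes, mark the rest unassigned. Greedy average
# linkage can fuse distinct modules low in the tree; recursion re-examines
# each branch with a tree rebuilt from its own dissimilarities.
split_branch <- function(d, genes, min_size, prefix = "m") {
  cl <- adaptive_height_cut(d[genes, genes, drop = FALSE], min_size)
  sizes <- table(cl)
  big <- names(sizes[sizes >= min_size])
  if (length(big) < 2) {
    return(setNames(rep(prefix, length(genes)), genes))
  }
  out <- setNames(rep("grey", length(genes)), genes)
  for (i in seq_along(big)) {
    g <- genes[cl == big[i]]
    out[g] <- if (length(g) >= 2L * min_size) {
      split_branch(d, g, min_size, paste0(prefix, "_", i))
    } else {
      setNames(rep(paste0(prefix, "_", i), length(g)), g)
    }
  }
  out
}

#' Refine a module partition by signed eigengene membership
#'
#' Iteratively reassigns every gene to the module whose eigengene it
#' correlates with most (signed Pearson kME), dropping genes whose best
#' membership falls below `kme_min` to grey and dissolving modules that
#' shrink below `min_size`, until a fixed point. This is the
#' membership-based clean-up step commonly applied after a tree cut: it
#' rescues stragglers the greedy dendrogram placed badly.
#'
#' @param expr Genes x samples matrix covering the partition's genes.
#' @param partition Tibble (gene, module).
#' @param kme_min Minimum signed membership to stay in a module
#'   (default 0.3).
#' @param min_size Minimum module size (default 30).
#' @param max_iter Iteration cap (default 20).
#' @return The refined partition tibble.
#' @export
refine_modules_kme <- function(expr, partition, kme_min = 0.3,
                               min_size = 30L, max_iter = 20L) {
  for (i in seq_len(max_iter)) {
    mods <- sort(setdiff(unique(partition$module), "grey"))
    if (length(mods) < 1) return(partition)
    eg <- module_eigengenes(expr, partition)
    kme <- cor(t(expr[partition$gene, , drop = FALSE]),
               eg$me[, mods, drop = FALSE])
    best <- max.col(kme, ties.method = "first")
    new_mod <- ifelse(kme[cbind(seq_along(best), best)] >= kme_min,
                      mods[best], "grey")
    if (all(new_mod == partition$module)) break
    partition$module <- new_mod
    sizes <- table(partition$module)
    small <- setdiff(names(sizes[sizes < min_size]), "grey")
    partition$module[partition$module %in% small] <- "grey"
  }
  partition
}

#' Detect modules from a TOM dissimilarity
#'
#' The package's full module-detection procedure: (1) recursive adaptive
#' tree cut — each branch is cut at the height yielding the most clusters
#' of at least `min_module_size` genes, and large clusters are re-examined
#' with a tree rebuilt from their own dissimilarities (greedy average
#' linkage at small sample sizes otherwise fuses distinct modules);
#' (2) leftover rescue — unassigned genes are re-clustered until no further
#' module-sized cluster emerges; (3) signed-kME refinement
#' ([refine_modules_kme()]); (4) eigengene-based merging
#' ([merge_close_modules()]); (5) a final refinement pass. Modules are then
#' named by decreasing size in the canonical colour order.
#'
#' @param expr Genes x samples matrix (rows must match `dissimilarity`).
#' @param dissimilarity Symmetric `1 - TOM` matrix with gene dimnames.
#' @param min_module_size Minimum module size (default 30).
#' @param merge_cut Eigengene-dissimilarity merge threshold (default 0.25).
#' @param kme_min Membership floor for the refinement stages.
#' @return Tibble: gene, module (canonical colours; "grey" = unassigned).
#' @export
detect_modules <- function(expr, dissimilarity, min_module_size = 30L,
                           merge_cut = 0.25, kme_min = 0.3) {
  stop_if_not_matrix(dissimilarity)
  genes <- rownames(dissimilarity)
  lab <- split_branch(dissimilarity, genes, min_module_size)
  partition <- tibble::tibble(gene = names(lab), module = unname(lab))
  sizes <- table(partition$module)
  small <- names(sizes[sizes < min_module_size])
  partition$module[partition$module %in% small] <- "grey"
  for (round in 1:10) {
    greys <- partition$gene[partition$module == "grey"]
    if (length(greys) < min_module_size) break
    lab2 <- split_branch(dissimilarity, greys, min_module_size,
                         prefix = paste0("r", round))
    sizes2 <- table(lab2)
    big <- names(sizes2[sizes2 >= min_module_size])
    if (length(big) == 0) break
    for (b in big) {
      partition$module[partition$gene %in% names(lab2)[lab2 == b]] <- b
    }
    if (length(big) == 1 && sum(lab2 %in% big) == length(greys)) break
  }
  if (all(partition$module == "grey")) return(partition)
  partition <- refine_modules_kme(expr, partition, kme_min, min_module_size)
  partition <- merge_close_modules(expr, partition, merge_cut)
  partition <- refine_modules_kme(expr, partition, kme_min, min_module_size)
  rename_modules(partition)
}

# Relabel non-grey modules by decreasing size with the canonical colours;
# ties broken by the lexicographically smallest member gene.
rename_modules <- function(partition) {
  info <- partition |>
    dplyr::filter(.data$module != "grey") |>
    dplyr::group_by(.data$module) |>
    dplyr::summarise(size = dplyr::n(), first_gene = min(.data$gene),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$size), .data$first_gene)
  if (nrow(info) == 0) return(partition)
  map <- setNames(module_colors(nrow(info)), info$module)
  partition$module <- ifelse(partition$module == "grey", "grey",
                             unname(map[partition$module]))
  partition
}

#' Merge modules with similar eigengenes
#'
#' Iteratively merges the closest pair of modules whose eigengene
#' dissimilarity `1 - cor(ME_a, ME_b)` falls below `merge_cut`,
#' recomputing eigengenes after each merge until no pair qualifies.
#' The absorbed module takes the label of the larger partner; "grey" never
#' participates.
#'
#' @param expr Genes x samples matrix.
#' @param partition Tibble (gene, module).
#' @param merge_cut Eigengene dissimilarity threshold (default 0.25).
#' @return The merged partition tibble.
#' @export
merge_close_modules <- function(expr, partition, merge_cut = 0.25) {
  if (merge_cut <= 0 || merge_cut >= 1) {
    stop("`merge_cut` must lie in (0, 1)", call. = FALSE)
  }
  repeat {
    mods <- sort(unique(partition$module[partition$module != "grey"]))
    if (length(mods) < 2) break
    eg <- module_eigengenes(expr, partition)
    d <- 1 - cor(eg$me[, mods, drop = FALSE])
    diag(d) <- Inf
    if (min(d) >= merge_cut) break
    ij <- which(d == min(d), arr.ind = TRUE)[1, ]
    a <- mods[ij[1]]; b <- mods[ij[2]]
    sz <- table(partition$module)
    keep <- if (sz[[a]] >= sz[[b]]) a else b
    drop <- setdiff(c(a, b), keep)
    partition$module[partition$module == drop] <- keep
  }
  partition
}

#' Build the full coexpression network
#'
#' One call from a normalized expression matrix to a module partition:
#' top-variance gene selection, soft-threshold choice (unless `power` is
#' given), adjacency, TOM, average-linkage clustering of `1 - TOM`, static
#' tree cut with a minimum module size, eigengene-based module merging, and
#' final eigengenes.
#'
#' @param normalized Log-normalized genes x samples matrix.
#' @param top_n Number of top-SD genes entering the network (default 5000,
#'   capped at the gene count).
#' @param power Soft-threshold power; `NULL` (default) to choose via
#'   [pick_soft_threshold()].
#' @param powers Candidate powers when `power` is `NULL`.
#' @param min_module_size,cut_quantile See [cut_gene_tree()].
#' @param merge_cut See [merge_close_modules()].
#' @param mode Network type ("unsigned" or "signed").
#' @param method Module detection: "hybrid" (default; the recursive
#'   adaptive cut with kME refinement of [detect_modules()]) or "static"
#'   (plain fixed-height cut of [cut_gene_tree()] followed by merging).
#' @return A `coex_network` object: list with elements `genes`, `power`,
#'   `soft_threshold`, `tom`, `dissimilarity`, `tree`, `partition`,
#'   `eigengenes`.
#' @export
build_network <- function(normalized, top_n = 5000L, power = NULL,
                          powers = 1:20, min_module_size = 30L,
                          cut_quantile = 0.99, merge_cut = 0.25,
                          mode = "unsigned",
                          method = c("hybrid", "static")) {
  method <- match.arg(method)
  genes <- top_variable_genes(normalized, min(top_n, nrow(normalized)))
  expr <- normalized[genes, , drop = FALSE]
  st <- NULL
  if (is.null(power)) {
    st <- pick_soft_threshold(expr, powers, mode = mode)
    power <- st$power
  }
  a <- wgcna_adjacency(expr, power, mode)
  tom <- tom_similarity(a)
  d <- 1 - tom
  diag(d) <- 0
  tree <- cluster_gene_tree(d)
  part <- if (method == "hybrid") {
    detect_modules(expr, d, min_module_size, merge_cut)
  } else {
    p0 <- cut_gene_tree(tree, min_module_size, cut_quantile)
    rename_modules(merge_close_modules(expr, p0, merge_cut))
  }
  eg <- if (any(part$module != "grey")) module_eigengenes(expr, part) else NULL
  structure(
    list(genes = genes, power = power, soft_threshold = st, tom = tom,
         dissimilarity = d, tree = tree, partition = part, eigengenes = eg,
         expr = expr),
    class = "coex_network"
  )
}

#' @export
print.coex_network <- function(x, ...) {
  nmod <- length(setdiff(unique(x$partition$module), "grey"))
  cat("<coex_network> ", length(x$genes), " genes, power = ", x$power,
      ", ", nmod, " module(s), ",
      sum(x$partition$module == "grey"), " grey gene(s)\n", sep = "")
  invisible(x)
}

#' @export
print.soft_threshold <- function(x, ...) {
  cat("<soft_threshold> chosen power =", x$power, "\n")
  print(x$report, n = 5)
  invisible(x)
}
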