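#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generator: planted
#' coexpression modules, differential-expression effects, the negative
#' binomial count model, per-gene SNP/LD structure, and planted causal GWAS
#' genes. The defaults describe a desk-scale study of the same shape as the
#' atrial-appendage design the pipeline targets: two groups (AF vs SR) of
#' five samples per tissue, RNA-seq-like counts, and two GWAS sets sharing
#' the same causal genes.
#'
#' @param seed Integer seed; the single source of randomness. Sub-streams
#'   (expression per tissue, each GWAS set, gene sets) derive their own seeds
#'   from it, so stages are independently reproducible.
#' @param n_genes Total number of genes.
#' @param n_samples_per_group Samples per group (AF and SR each).
#' @param module_spec Data frame with columns `module_size`,
#'   `latent_correlation` (fraction of a module gene's log-scale variance
#'   carried by the shared latent factor, in (0,1)) and `trait_effect`
#'   (shift of the latent factor in the AF group, in latent SD units).
#'   Module genes occupy the first `sum(module_size)` gene indices.
#' @param de_spec Data frame with columns `gene` (index) and `log2fc`
#'   (AF-vs-SR log2 fold change added on the log2 mean scale).
#' @param nb_dispersion Negative-binomial dispersion (1/size), shared across
#'   genes.
#' @param baseline_mean Median of the log-normal gene baseline means.
#' @param snp_spec List with `n_snps` (SNPs per gene), `n_ld_blocks`
#'   (LD blocks per gene), `within_block_r2` (constant R2 inside a block)
#'   and `n_intergenic` (background SNPs outside genes).
#' @param causal_genes Data frame with columns `gene` (index) and `p_scale`
#'   (target minimum SNP p-value scale for that gene, e.g. 1e-8).
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 1000L,
                       n_samples_per_group = 5L,
                       module_spec = data.frame(
                         module_size = c(100L, 100L),
                         latent_correlation = c(0.8, 0.8),
                         trait_effect = c(2, 0)
                       ),
                       de_spec = data.frame(gene = integer(), log2fc = numeric()),
                       nb_dispersion = 0.05,
                       baseline_mean = 100,
                       snp_spec = list(n_snps = 8L, n_ld_blocks = 2L,
                                       within_block_r2 = 0.9,
                                       n_intergenic = 200L),
                       causal_genes = data.frame(gene = integer(),
                                                 p_scale = numeric())) {
  module_spec <- tibble::as_tibble(module_spec)
  de_spec <- tibble::as_tibble(de_spec)
  causal_genes <- tibble::as_tibble(causal_genes)
  if (n_genes < 1 || n_samples_per_group < 1) {
    stop("`n_genes` and `n_samples_per_group` must be positive", call. = FALSE)
  }
  if (nrow(module_spec) > 0) {
    if (sum(module_spec$module_size) > n_genes) {
      stop("sum of module sizes exceeds `n_genes`", call. = FALSE)
    }
    if (any(module_spec$latent_correlation <= 0 |
            module_spec$latent_correlation >= 1)) {
      stop("`latent_correlation` must lie in (0, 1)", call. = FALSE)
    }
    if (any(module_spec$module_size < 2)) {
      stop("module sizes must be at least 2", call. = FALSE)
    }
  }
  if (nb_dispersion <= 0 || baseline_mean <= 0) {
    stop("`nb_dispersion` and `baseline_mean` must be positive", call. = FALSE)
  }
  if (nrow(de_spec) > 0 && any(de_spec$gene < 1 | de_spec$gene > n_genes)) {
    stop("`de_spec` gene indices out of range", call. = FALSE)
  }
  if (nrow(causal_genes) > 0 &&
      any(causal_genes$gene < 1 | causal_genes$gene > n_genes)) {
    stop("`causal_genes` indices out of range", call. = FALSE)
  }
  if (snp_spec$n_snps < 1 && nrow(causal_genes) > 0) {
    stop("causal genes require at least one SNP per gene", call. = FALSE)
  }
  if (snp_spec$within_block_r2 < 0 || snp_spec$within_block_r2 > 1) {
    stop("`within_block_r2` must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(seed = as.integer(seed), n_genes = as.integer(n_genes),
         n_samples_per_group = as.integer(n_samples_per_group),
         module_spec = module_spec, de_spec = de_spec,
         nb_dispersion = nb_dispersion, baseline_mean = baseline_mean,
         snp_spec = snp_spec, causal_genes = causal_genes),
    class = "sim_config"
  )
}

gene_ids <- function(n) sprintf("g%05d", seq_len(n))

# Gene -> planted module label, "background" otherwise. Module m gets the
# canonical colour name of rank m by size so sets/partitions line up.
planted_modules <- function(config) {
  lab <- rep("background", config$n_genes)
  if (nrow(config$module_spec) > 0) {
    ord <- order(-config$module_spec$module_size,
                 seq_len(nrow(config$module_spec)))
    cols <- character(nrow(config$module_spec))
    cols[ord] <- module_colors(nrow(config$module_spec))
    idx <- 1L
    for (m in seq_len(nrow(config$module_spec))) {
      sz <- config$module_spec$module_size[m]
      lab[idx:(idx + sz - 1L)] <- cols[m]
      idx <- idx + sz
    }
  }
  tibble::tibble(gene = gene_ids(config$n_genes), module = lab)
}

#' Simulate an RNA-seq count matrix with planted coexpression modules
#'
#' Counts are negative binomial around log-normal gene baselines. Genes in a
#' planted module share a per-sample latent factor: on the log2 scale a
#' module gene is `sigma * (a_g * z + sqrt(1 - a_g^2) * eps)` around its
#' baseline, where `z` is the module factor (shifted by `trait_effect` in
#' the AF group) and the per-gene loading `a_g` is centred on
#' `sqrt(latent_correlation)` with a moderate spread, so modules have hubs
#' and periphery as real coexpression modules do (this is also what couples
#' module membership to trait-driven differential expression). Background
#' genes get independent low-amplitude noise. Differential expression from
#' `de_spec` adds `log2fc` to the log2 mean of AF samples.
#'
#' @param config A [sim_config()].
#' @param tissue Tissue label recorded in the metadata ("LAA" or "RAA");
#'   different tissues are independent draws sharing the same ground truth.
#' @return List with `counts` (genes x samples integer matrix),
#'   `metadata` (tibble: sample, group, tissue) and `truth` (tibble:
#'   gene, module, log2fc).
#' @export
simulate_expression <- function(config, tissue = "LAA") {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_samples_per_group
  ng <- config$n_genes
  groups <- rep(c("SR", "AF"), each = n)
  samples <- sprintf("%s_%s_%d", tissue, groups, c(seq_len(n), seq_len(n)))
  truth <- planted_modules(config)
  truth$log2fc <- 0
  if (nrow(config$de_spec) > 0) truth$log2fc[config$de_spec$gene] <- config$de_spec$log2fc

  sigma_module <- 1.2   # log2-SD of module-gene signal
  sigma_bg <- 0.4       # log2-SD of background-gene noise

  counts <- with_seed(substream_seed(config$seed, paste0("expression_", tissue)), {
    base <- 2^rnorm(ng, mean = log2(config$baseline_mean), sd = 1)
    log2mu <- matrix(log2(base), nrow = ng, ncol = 2L * n)
    if (nrow(config$module_spec) > 0) {
      idx <- 1L
      for (m in seq_len(nrow(config$module_spec))) {
        sz <- config$module_spec$module_size[m]
        rho <- config$module_spec$latent_correlation[m]
        z <- rnorm(2L * n) + config$module_spec$trait_effect[m] * (groups == "AF")
        eps <- matrix(rnorm(sz * 2L * n), nrow = sz)
        # hub-to-periphery spread of loadings around sqrt(rho)
        a <- pmin(sqrt(rho) * runif(sz, 0.85, 1.15), 0.99)
        sig <- sigma_module *
          (a * matrix(z, nrow = sz, ncol = 2L * n, byrow = TRUE) +
             sqrt(1 - a^2) * eps)
        log2mu[idx:(idx + sz - 1L), ] <- log2mu[idx:(idx + sz - 1L), ] + sig
        idx <- idx + sz
      }
      bg <- idx:ng
    } else {
      bg <- seq_len(ng)
    }
    if (length(bg) > 0 && bg[1] <= ng) {
      log2mu[bg, ] <- log2mu[bg, ] +
        sigma_bg * matrix(rnorm(length(bg) * 2L * n), nrow = length(bg))
    }
    log2mu <- log2mu + outer(truth$log2fc, as.numeric(groups == "AF"))
    k <- matrix(rnbinom(ng * 2L * n, mu = 2^log2mu, size = 1 / config$nb_dispersion),
                nrow = ng)
    storage.mode(k) <- "integer"
    k
  })
  dimnames(counts) <- list(truth$gene, samples)
  metadata <- tibble::tibble(sample = samples, group = groups, tissue = tissue)
  list(counts = counts, metadata = metadata, truth = truth)
}

#' Simulate a gene annotation table
#'
#' Genes are laid out in order along chromosomes 1..22 with random lengths
#' and intergenic gaps; strand alternates at random. Coordinates are 1-based
#' inclusive.
#'
#' @param config A [sim_config()].
#' @return Tibble: gene, chrom, start, end, strand.
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ng <- config$n_genes
  with_seed(substream_seed(config$seed, "annotation"), {
    chrom <- paste0("chr", sort(rep_len(1:22, ng)))
    len <- sample(10000:60000, ng, replace = TRUE)
    gap <- sample(50000:200000, ng, replace = TRUE)
    start <- integer(ng)
    pos <- 1L
    last_chr <- ""
    for (i in seq_len(ng)) {
      if (chrom[i] != last_chr) { pos <- 1L; last_chr <- chrom[i] }
      start[i] <- pos + gap[i]
      pos <- start[i] + len[i]
    }
    tibble::tibble(gene = gene_ids(ng), chrom = chrom, start = start,
                   end = start + len,
                   strand = sample(c("+", "-"), ng, replace = TRUE))
  })
}

#' Simulate GWAS summary statistics and an LD-pair table
#'
#' Places `n_snps` SNPs uniformly inside each gene body plus intergenic
#' background SNPs. Within each gene the SNPs are split (by position) into
#' `n_ld_blocks` contiguous blocks, and every within-block pair is emitted
#' with the constant configured R2; between-block and intergenic pairs are
#' absent (R2 = 0). Null p-values are marginally Uniform(0,1) but
#' correlated within a block, mirroring how linked genotypes share an
#' association statistic: each block draws a latent standard-normal factor,
#' each SNP's z is `sqrt(R2) * z_block + sqrt(1 - R2) * noise`, and
#' p = 2 * pnorm(-|z|). Each planted causal gene additionally gets one SNP
#' whose p-value is drawn at the configured scale (`p_scale * U(0.1, 1)`,
#' hence always at or below `p_scale`).
#'
#' @param config A [sim_config()].
#' @param annotation Gene annotation tibble from [simulate_annotation()];
#'   must cover all genes referenced by `causal_genes`.
#' @param set Label selecting an independent random sub-stream, so that
#'   "discovery" and "test" GWAS sets share causal genes but nothing else.
#' @return List with `snps` (tibble: chrom, pos, snp, p), `ld` (tibble:
#'   snp_a, snp_b, r2) and `truth` (tibble: snp, gene, ld_block).
#' @export
simulate_gwas <- function(config, annotation, set = "discovery") {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(config$causal_genes) > 0) {
    cg <- gene_ids(config$n_genes)[config$causal_genes$gene]
    if (!all(cg %in% annotation$gene)) {
      stop("annotation does not cover all causal genes", call. = FALSE)
    }
    if (config$snp_spec$n_snps < 1) {
      stop("causal gene without SNPs: `n_snps` must be >= 1", call. = FALSE)
    }
  }
  sp <- config$snp_spec
  with_seed(substream_seed(config$seed, paste0("gwas_", set)), {
    per_gene <- purrr::pmap(annotation, function(gene, chrom, start, end, strand) {
      pos <- sort(sample(start:end, sp$n_snps, replace = FALSE))
      nb <- max(1L, min(sp$n_ld_blocks, sp$n_snps))
      block <- sort(rep_len(seq_len(nb), sp$n_snps))
      tibble::tibble(gene = gene, chrom = chrom, pos = pos, ld_block = block)
    })
    snps <- dplyr::bind_rows(per_gene)
    snps$snp <- sprintf("rs%07d", seq_len(nrow(snps)))
    block_id <- paste(snps$gene, snps$ld_block)
    z_block <- rnorm(length(unique(block_id)))
    names(z_block) <- unique(block_id)
    z <- sqrt(sp$within_block_r2) * z_block[block_id] +
      sqrt(1 - sp$within_block_r2) * rnorm(nrow(snps))
    snps$p <- 2 * pnorm(-abs(unname(z)))
    if (nrow(config$causal_genes) > 0) {
      for (i in seq_len(nrow(config$causal_genes))) {
        g <- gene_ids(config$n_genes)[config$causal_genes$gene[i]]
        rows <- which(snps$gene == g)
        hit <- rows[sample.int(length(rows), 1L)]
        snps$p[hit] <- config$causal_genes$p_scale[i] * runif(1, 0.1, 1)
      }
    }
    inter <- tibble::tibble(
      gene = NA_character_,
      chrom = sample(paste0("chr", 1:22), sp$n_intergenic, replace = TRUE),
      pos = sample.int(3e7, sp$n_intergenic, replace = TRUE),
      ld_block = NA_integer_,
      snp = sprintf("bg%07d", seq_len(sp$n_intergenic)),
      p = runif(sp$n_intergenic)
    )
    all_snps <- dplyr::bind_rows(snps, inter)
    ld <- snps |>
      dplyr::filter(!is.na(.data$ld_block)) |>
      dplyr::group_by(.data$gene, .data$ld_block) |>
      dplyr::summarise(pairs = list({
        ids <- sort(.data$snp)
        if (length(ids) >= 2) {
          cmb <- combn(ids, 2)
          tibble::tibble(snp_a = cmb[1, ], snp_b = cmb[2, ])
        } else tibble::tibble(snp_a = character(), snp_b = character())
      }), .groups = "drop") |>
      tidyr::unnest("pairs") |>
      dplyr::transmute(.data$snp_a, .data$snp_b, r2 = sp$within_block_r2)
    list(
      snps = dplyr::select(all_snps, "chrom", "pos", "snp", "p"),
      ld = ld,
      truth = dplyr::select(all_snps, "snp", "gene", "ld_block")
    )
  })
}

#' Build gene sets from the simulation ground truth
#'
#' Emits one gene set per planted module (exactly its member genes) plus
#' `n_decoy` random sets drawn without replacement from all genes.
#'
#' @param truth Expression ground-truth tibble (gene, module) from
#'   [simulate_expression()].
#' @param n_decoy Number of random decoy sets.
#' @param decoy_size Size of each decoy set.
#' @param seed Seed for the decoy draw.
#' @return Named list of character vectors (GMT-writable).
#' @export
simulate_gene_sets <- function(truth, n_decoy = 5L, decoy_size = 30L, seed = 1L) {
  mods <- sort(unique(truth$module[truth$module != "background"]))
  sets <- lapply(mods, function(m) truth$gene[truth$module == m])
  names(sets) <- ifelse(mods == "", mods, paste0("MODULE_", toupper(mods)))
  decoys <- with_seed(substream_seed(seed, "gene_sets"), {
    lapply(seq_len(n_decoy), function(i) {
      sample(truth$gene, min(decoy_size, length(truth$gene)), replace = FALSE)
    })
  })
  names(decoys) <- sprintf("DECOY_%02d", seq_len(n_decoy))
  c(sets, decoys)
}
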