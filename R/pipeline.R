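#' Pipeline configuration
#'
#' All stage thresholds with the study defaults: LD R2 > 0.8, gene-bound
#' extensions 2000/1000 bp, adjusted-p threshold 0.05, top 5000 genes,
#' minimum module size 30, eigengene merge cut 0.25, TOM edge cutoff 0.15,
#' GS cut 2, GSEA FDR 0.25.
#'
#' @param sim A [sim_config()] describing the synthetic inputs.
#' @param outdir Output directory for all intermediate files; created if
#'   missing.
#' @param r2_threshold,five_prime_bp,three_prime_bp,alpha GWAS-stage
#'   parameters.
#' @param top_n,power,min_module_size,merge_cut,cut_quantile Network-stage
#'   parameters (`power = NULL` selects the soft threshold automatically).
#' @param edge_cutoff,gs_cut Core-gene-stage parameters.
#' @param gsea_fdr,gsea_nperm GSEA parameters.
#' @param tissues Tissue labels to analyze.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim, outdir,
                            r2_threshold = 0.8, five_prime_bp = 2000L,
                            three_prime_bp = 1000L, alpha = 0.05,
                            top_n = 5000L, power = NULL,
                            min_module_size = 30L, merge_cut = 0.25,
                            cut_quantile = 0.99, edge_cutoff = 0.15,
                            gs_cut = 2, gsea_fdr = 0.25, gsea_nperm = 200L,
                            tissues = c("LAA", "RAA")) {
  stopifnot(inherits(sim, "sim_config"))
  structure(
    list(sim = sim, outdir = outdir, r2_threshold = r2_threshold,
         five_prime_bp = five_prime_bp, three_prime_bp = three_prime_bp,
         alpha = alpha, top_n = top_n, power = power,
         min_module_size = min_module_size, merge_cut = merge_cut,
         cut_quantile = cut_quantile, edge_cutoff = edge_cutoff,
         gs_cut = gs_cut, gsea_fdr = gsea_fdr, gsea_nperm = gsea_nperm,
         tissues = tissues),
    class = "pipeline_config"
  )
}

#' Run the integrative pipeline end to end
#'
#' Simulates (or regenerates deterministically from the config seed) the
#' GWAS discovery and test sets, LD table, gene annotation, per-tissue
#' expression counts and gene sets; then per tissue: size-factor
#' normalization, PCA outlier screen, NB Wald differential expression,
#' coexpression network construction, module-trait contingency
#' coefficients, module membership and GS-MM association, GSEA, TOM edge
#' export for the trait-associated modules, and core-gene selection with
#' test-set confirmation. Every table is written under `config$outdir` and
#' recorded in a checksum manifest.
#'
#' @param config A [pipeline_config()].
#' @return List with per-tissue results (`de`, `network`, `module_trait`,
#'   `gs_mm`, `gsea`, `edges`, `report`), the cross-tissue `overlap`, the
#'   GWAS `discovery`/`test` score tables, and the `manifest` tibble
#'   (file, stage, checksum).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  emit <- function(x, name, stage, writer = readr::write_tsv) {
    path <- file.path(config$outdir, name)
    writer(x, path)
    manifest[[length(manifest) + 1]] <<- tibble::tibble(
      file = name, stage = stage,
      checksum = unname(tools::md5sum(path))
    )
    invisible(path)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage [", stage, "] failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  # --- simulate inputs ------------------------------------------------
  sim <- config$sim
  annotation <- run_stage("simulate", simulate_annotation(sim))
  gwas_dis <- run_stage("simulate", simulate_gwas(sim, annotation, "discovery"))
  gwas_test <- run_stage("simulate", simulate_gwas(sim, annotation, "test"))
  emit(annotation, "annotation.tsv", "simulate")
  emit(gwas_dis$snps, "gwas_discovery.tsv", "simulate")
  emit(gwas_test$snps, "gwas_test.tsv", "simulate")
  emit(gwas_dis$ld, "ld_discovery.tsv", "simulate")
  emit(gwas_test$ld, "ld_test.tsv", "simulate")

  # --- gene-level GWAS scores ----------------------------------------
  discovery <- run_stage("map-gwas", score_gwas_genes(
    gwas_dis$snps, gwas_dis$ld, annotation, config$r2_threshold,
    config$five_prime_bp, config$three_prime_bp, config$alpha))
  test <- run_stage("map-gwas", score_gwas_genes(
    gwas_test$snps, gwas_test$ld, annotation, config$r2_threshold,
    config$five_prime_bp, config$three_prime_bp, config$alpha))
  emit(discovery, "gene_scores_discovery.tsv", "map-gwas")
  emit(test, "gene_scores_test.tsv", "map-gwas")

  per_tissue <- list()
  gs_lists <- list()
  for (tissue in config$tissues) {
    ex <- run_stage("simulate", simulate_expression(sim, tissue))
    emit(ex$counts, paste0("counts_", tissue, ".tsv"), "simulate",
         writer = write_counts)
    emit(ex$metadata, paste0("metadata_", tissue, ".tsv"), "simulate")

    sf <- run_stage("de", size_factors(ex$counts))
    norm <- run_stage("de", normalize_log(ex$counts, sf))
    pca <- run_stage("de", pca_outlier_check(norm))
    de <- run_stage("de", de_test(ex$counts, ex$metadata))
    emit(de, paste0("de_", tissue, ".tsv"), "de")

    net <- run_stage("network", build_network(
      norm, top_n = config$top_n, power = config$power,
      min_module_size = config$min_module_size,
      cut_quantile = config$cut_quantile, merge_cut = config$merge_cut))
    emit(net$partition, paste0("modules_", tissue, ".tsv"), "network")

    mt <- run_stage("module-trait",
                    module_trait_cc(net$eigengenes, ex$metadata))
    emit(mt, paste0("module_trait_", tissue, ".tsv"), "module-trait")
    sig_mods <- mt$module[mt$p < 0.05]
    if (length(sig_mods) == 0) sig_mods <- mt$module[which.max(mt$cc)]

    mm <- run_stage("module-trait", module_membership(net$expr, net$eigengenes))
    gsmm <- run_stage("module-trait",
                      gs_mm_association(mm, de, net$partition))
    emit(gsmm, paste0("gs_mm_", tissue, ".tsv"), "module-trait")

    sets <- run_stage("gsea",
                      simulate_gene_sets(ex$truth, seed = sim$seed))
    ranked <- de |>
      dplyr::transmute(.data$gene, score = sign(.data$log2fc) * .data$gs)
    enr <- run_stage("gsea", gsea(
      ranked, sets, n_perm = config$gsea_nperm, seed = sim$seed,
      min_size = 5L, fdr_cut = config$gsea_fdr))
    emit(enr, paste0("gsea_", tissue, ".tsv"), "gsea")

    edges <- run_stage("core-genes", export_edges(
      net$tom, net$partition, sig_mods, config$edge_cutoff))
    emit(edges, paste0("edges_", tissue, ".tsv"), "core-genes",
         writer = write_edges)
    linked <- crosslinked_genes(edges)
    report <- run_stage("core-genes", de |>
      dplyr::filter(.data$gene %in% net$genes) |>
      select_core_genes(linked, discovery, config$gs_cut, config$alpha) |>
      confirm_with_test(test, config$alpha))
    emit(report, paste0("core_genes_", tissue, ".tsv"), "core-genes")

    mod_genes <- net$partition$gene[net$partition$module %in% sig_mods]
    gs_lists[[tissue]] <- intersect(mod_genes,
                                    de$gene[de$gs > config$gs_cut])
    per_tissue[[tissue]] <- list(
      size_factors = sf, pca = pca, de = de, network = net,
      module_trait = mt, significant_modules = sig_mods, gs_mm = gsmm,
      gsea = enr, edges = edges, report = report)
  }

  overlap <- if (length(gs_lists) >= 2) {
    overlap_gene_lists(gs_lists[[1]], gs_lists[[2]])
  } else NULL
  if (!is.null(overlap)) emit(overlap, "overlap.tsv", "core-genes")

  manifest <- dplyr::bind_rows(manifest)
  emit_path <- file.path(config$outdir, "manifest.tsv")
  readr::write_tsv(manifest, emit_path)
  list(tissues = per_tissue, overlap = overlap, discovery = discovery,
       test = test, annotation = annotation, manifest = manifest)
}
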