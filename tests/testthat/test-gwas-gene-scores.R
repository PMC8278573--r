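toy_annotation <- function() {
  tibble::tibble(gene = c("A", "B"), chrom = "chr1",
                 start = c(10000L, 11000L), end = c(12000L, 13000L),
                 strand = c("+", "-"))
}

test_that("gene bounds extend strand-specifically and floor at 1", {
  ann <- tibble::tibble(gene = c("plus", "minus"), chrom = "chr1",
                        start = 10000L, end = 12000L,
                        strand = c("+", "-"))
  ext <- extend_gene_bounds(ann, 2000, 1000)
  expect_equal(ext$start, c(8000, 9000))
  expect_equal(ext$end, c(13000, 14000))
  expect_equal(extend_gene_bounds(ann, 0, 0)[, c("start", "end")],
               ann[, c("start", "end")])
  near_edge <- tibble::tibble(gene = "E", chrom = "chr1", start = 500L,
                              end = 900L, strand = "+")
  expect_equal(extend_gene_bounds(near_edge, 2000, 0)$start, 1)
  expect_error(extend_gene_bounds(ann, -1, 0), "non-negative")
})

test_that("SNPs map to genes by inclusive containment, overlaps included", {
  ext <- extend_gene_bounds(
    tibble::tibble(gene = "A", chrom = "chr1", start = 10000L, end = 12000L,
                   strand = "+"), 2000, 1000)
  snps <- tibble::tibble(chrom = "chr1", pos = c(8000L, 7999L, 13000L, 13001L),
                         snp = paste0("s", 1:4), p = 0.5)
  hits <- assign_snps(snps, ext)
  expect_setequal(hits$snp, c("s1", "s3"))
  # a SNP inside two overlapping genes is counted under both
  both <- assign_snps(tibble::tibble(chrom = "chr1", pos = 11500L,
                                     snp = "s", p = 0.1), toy_annotation())
  expect_setequal(both$gene, c("A", "B"))
  expect_error(assign_snps(tibble::tibble(chrom = "chr 1!", pos = 1L,
                                          snp = "s", p = 0.1),
                           toy_annotation()), "chromosome")
})

test_that("proxy clusters are connected components above the R2 threshold", {
  ld3 <- tibble::tibble(snp_a = c("s1", "s1", "s2"),
                        snp_b = c("s2", "s3", "s3"), r2 = 0.9)
  expect_equal(cluster_proxies(c("s1", "s2", "s3"), ld3, 0.8), 1)
  no_ld <- tibble::tibble(snp_a = character(), snp_b = character(),
                          r2 = numeric())
  expect_equal(cluster_proxies(c("s1", "s2", "s3"), no_ld, 0.8), 3)
  chain <- tibble::tibble(snp_a = c("s1", "s2", "s1"),
                          snp_b = c("s2", "s3", "s3"),
                          r2 = c(0.9, 0.9, 0.5))
  expect_equal(cluster_proxies(c("s1", "s2", "s3"), chain, 0.8), 1)
  # strictly greater-than: R2 exactly at the threshold is not linkage
  at <- tibble::tibble(snp_a = "s1", snp_b = "s2", r2 = 0.8)
  expect_equal(cluster_proxies(c("s1", "s2"), at, 0.8), 2)
  expect_error(cluster_proxies(character(), ld3, 0.8), "empty")
})

test_that("cluster count matches a union-find oracle and ignores labels", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(3:100, 1)
    ids <- paste0("v", sample(1e6, n))
    n_pairs <- sample(0:min(200, n * 2), 1)
    pairs <- cbind(sample(ids, n_pairs, replace = TRUE),
                   sample(ids, n_pairs, replace = TRUE))
    pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
    r2 <- runif(nrow(pairs))
    ld <- tibble::tibble(snp_a = pairs[, 1], snp_b = pairs[, 2], r2 = r2)
    k <- cluster_proxies(ids, ld, 0.8)
    expect_equal(k, union_find_components(ids, pairs, r2, 0.8))
    # relabeling SNP ids and shuffling pair order leaves k unchanged
    perm <- setNames(paste0("w", seq_along(ids)), ids)
    ld2 <- tibble::tibble(snp_a = unname(perm[ld$snp_a]),
                          snp_b = unname(perm[ld$snp_b]), r2 = ld$r2)
    ld2 <- ld2[sample(nrow(ld2)), ]
    expect_equal(cluster_proxies(unname(perm[ids]), ld2, 0.8), k)
  }
})

test_that("Sidak adjustment matches its closed form and the Bonferroni sandwich", {
  expect_equal(gene_adjusted_p(0.01, 1), 0.01)
  expect_equal(gene_adjusted_p(c(0, 0.3), 7), 0)
  expect_equal(gene_adjusted_p(0.01, 5), 0.04900995, tolerance = 1e-5 / 0.049)
  expect_error(gene_adjusted_p(0.01, 0), "k")
  expect_error(gene_adjusted_p(numeric(0), 2), "empty")
  set.seed(7)
  for (rep in 1:50) {
    p <- runif(sample(1:10, 1))
    k <- sample(1:20, 1)
    adj <- gene_adjusted_p(p, k)
    expect_gte(adj, min(p))
    expect_lte(adj, min(1, k * min(p)))
  }
})

test_that("BH q-values match the hand step-up recursion", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(8)
  for (rep in 1:20) {
    p <- runif(sample(1:50, 1))
    q <- bh_fdr(p)
    expect_equal(q, bh_by_hand(p))
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("gene scoring flags planted causal genes and stays calibrated on nulls", {
  cfg <- planted_pipeline_config()
  ann <- simulate_annotation(cfg)
  g <- simulate_gwas(cfg, ann)
  scores <- score_gwas_genes(g$snps, g$ld, ann)
  causal <- sprintf("g%05d", 1:5)
  expect_true(all(scores$flagged[scores$gene %in% causal]))
  expect_true(all(scores$p_adj >= scores$p_min - 1e-12))
  expect_true(all(scores$k <= scores$n_snps))
  expect_true(all(scores$q >= scores$p_adj - 1e-12))
  # causal genes rank far below nulls
  expect_lt(median(scores$p_adj[scores$gene %in% causal]),
            median(scores$p_adj[!scores$gene %in% causal]))
  # independent SNPs (one per LD block) make the Sidak correction exact
  null_cfg <- sim_config(seed = 23, n_genes = 500,
                         module_spec = data.frame(
                           module_size = integer(),
                           latent_correlation = numeric(),
                           trait_effect = numeric()),
                         snp_spec = list(n_snps = 6L, n_ld_blocks = 6L,
                                         within_block_r2 = 0.9,
                                         n_intergenic = 100L))
  ann0 <- simulate_annotation(null_cfg)
  g0 <- simulate_gwas(null_cfg, ann0)
  s0 <- score_gwas_genes(g0$snps, g0$ld, ann0)
  expect_lte(mean(s0$flagged), 0.10)
  expect_true(all(score_gwas_genes(g0$snps, g0$ld, ann0, alpha = 1)$flagged))
})
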