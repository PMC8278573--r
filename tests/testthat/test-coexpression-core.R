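# Deterministic expression matrix whose gene profiles are exact linear
# combinations of orthonormal basis vectors, so pairwise correlations (and
# hence eigengene geometry) are controlled exactly.
basis_expr <- function(loadings, n_samples = 40, gene_prefix = "g") {
  q <- qr.Q(qr(matrix(sin(seq_len(n_samples * ncol(loadings)) * 0.7),
                      n_samples)))
  x <- q %*% t(loadings)
  x <- t(x)
  rownames(x) <- paste0(gene_prefix, sprintf("%03d", seq_len(nrow(x))))
  colnames(x) <- paste0("s", seq_len(ncol(x)))
  x
}

test_that("adjacency is the soft-powered correlation", {
  s <- seq_len(10)
  expr <- rbind(a = s, b = 2 * s + 3, c = -s, d = c(s[-1], 1))
  colnames(expr) <- paste0("s", 1:10)
  a1 <- wgcna_adjacency(expr, 1)
  expect_equal(unname(a1), unname(abs(cor(t(expr)))))
  a18 <- wgcna_adjacency(expr, 18)
  expect_equal(a18["a", "b"], 1)
  expect_equal(a18["a", "c"], 1)
  r <- abs(cor(expr["a", ], expr["d", ]))
  expect_equal(a18["a", "d"], r^18)
  expect_equal(unname(wgcna_adjacency(rbind(a = s, b = 2 * s), 3,
                                      mode = "signed")["a", "b"]), 1)
  expr_const <- rbind(expr, e = rep(1, 10))
  expect_error(wgcna_adjacency(expr_const, 2), "e")
  # a correlation of 0.5 at power 18 is vanishingly small
  expect_equal(0.5^18, 3.8147e-06, tolerance = 1e-4)
})

test_that("soft-threshold search reports monotone connectivity and honors singletons", {
  ex <- simulate_expression(one_module_config(seed = 7))
  norm <- normalize_log(ex$counts)
  st <- pick_soft_threshold(norm, powers = c(1, 2, 4, 8, 16))
  expect_true(all(diff(st$report$k_mean) < 0))
  expect_s3_class(tidy(st), "tbl_df")
  expect_equal(sum(tidy(st)$chosen), 1L)
  single <- pick_soft_threshold(norm, powers = 6)
  expect_equal(single$power, 6)
})

test_that("soft threshold lands in the moderate range on modular data", {
  ex <- simulate_expression(four_module_config(seed = 3))
  norm <- normalize_log(ex$counts)
  st <- pick_soft_threshold(norm, powers = 1:20)
  expect_lte(st$power, 12)
  expect_gte(st$report$fit_r2[st$report$power == st$power], 0.8)
})

test_that("TOM matches hand-derived values and the triple-loop oracle", {
  triangle <- matrix(1, 3, 3)
  expect_equal(unname(tom_similarity(triangle)), matrix(1, 3, 3))
  pair <- diag(3)
  pair[1, 2] <- pair[2, 1] <- 0.5
  expect_equal(tom_similarity(pair)[1, 2], 0.5)
  expect_equal(unname(tom_similarity(diag(3))), diag(3))
  set.seed(5)
  for (n in c(5, 20, 50)) {
    a <- matrix(runif(n * n), n)
    a <- (a + t(a)) / 2
    diag(a) <- 1
    tom <- tom_similarity(a)
    expect_equal(tom, tom_triple_loop(a), tolerance = 1e-12)
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
    expect_true(isSymmetric(tom))
  }
  expect_error(tom_similarity(matrix(runif(9), 3)), "symmetric")
})

test_that("the average-linkage tree merges duplicates first with monotone heights", {
  d <- matrix(c(0, 0, 0.9, 0.8,
                0, 0, 0.9, 0.8,
                0.9, 0.9, 0, 0.1,
                0.8, 0.8, 0.1, 0), 4,
              dimnames = list(paste0("g", 1:4), paste0("g", 1:4)))
  tree <- cluster_gene_tree(d)
  expect_equal(tree$height[1], 0)
  expect_true(all(diff(tree$height) >= 0))
  # the two well-separated pairs merge internally before joining
  expect_equal(sort(cutree(tree, k = 2)), sort(c(g1 = 1, g2 = 1, g3 = 2, g4 = 2)))
  dn <- d; dn[1, 2] <- NaN
  expect_error(cluster_gene_tree(dn), "NA")
})

test_that("the static cut respects the minimum module size and colour order", {
  block <- function(n, lo, hi) {
    m <- matrix(runif(n * n, lo, hi), n); (m + t(m)) / 2
  }
  set.seed(12)
  d <- matrix(runif(80 * 80, 0.85, 1), 80)
  d <- (d + t(d)) / 2
  d[1:40, 1:40] <- block(40, 0.05, 0.25)
  d[41:80, 41:80] <- block(40, 0.05, 0.30)
  diag(d) <- 0
  dimnames(d) <- list(paste0("g", sprintf("%02d", 1:80)),
                      paste0("g", sprintf("%02d", 1:80)))
  part <- cut_gene_tree(cluster_gene_tree(d), min_module_size = 30,
                        cut_quantile = 0.7)
  expect_setequal(unique(part$module), c("turquoise", "blue"))
  expect_equal(unname(table(part$module)["turquoise"]), 40L,
               ignore_attr = TRUE)
  # a 20-gene block cannot form a module at minModuleSize 30
  d20 <- d[1:60, 1:60]
  d20[1:20, 21:60] <- 0.95; d20[21:60, 1:20] <- 0.95
  d20[21:60, 21:60] <- 0.95; diag(d20) <- 0
  part20 <- cut_gene_tree(cluster_gene_tree(d20), min_module_size = 30,
                          cut_quantile = 0.7)
  expect_true(all(part20$module[1:20] == "grey"))
  # largest cluster takes the first canonical colour
  d2 <- d
  d2[41:80, 41:80][1:5, ] <- 0.9; d2[41:80, 41:80][, 1:5] <- 0.9
  d2[41:80, 41:80][1:5, 1:5] <- 0.1; diag(d2) <- 0
  d2 <- (d2 + t(d2)) / 2; diag(d2) <- 0
  p2 <- cut_gene_tree(cluster_gene_tree(d2), min_module_size = 30,
                      cut_quantile = 0.7)
  sizes <- table(p2$module[p2$module != "grey"])
  expect_equal(names(which.max(sizes)), "turquoise")
})

test_that("module eigengenes capture the module factor", {
  # a rank-one module: every gene is the same profile (scaled/shifted)
  s <- sin(seq_len(20))
  expr <- rbind(a = s, b = 2 * s + 1, c = -3 * s)
  colnames(expr) <- paste0("s", 1:20)
  part <- tibble::tibble(gene = c("a", "b", "c"), module = "turquoise")
  eg <- module_eigengenes(expr, part)
  expect_equal(unname(eg$var_explained["turquoise"]), 1)
  expect_equal(abs(cor(eg$me[, 1], s)), 1)
  # flipping every gene's sign leaves |cor(ME, trait)| unchanged
  eg2 <- module_eigengenes(-expr, part)
  trait <- rep(c(0, 1), 10)
  expect_equal(abs(cor(eg$me[, 1], trait)), abs(cor(eg2$me[, 1], trait)))
  # orthogonal planted factors give near-orthogonal eigengenes
  load <- rbind(matrix(rep(c(1, 0), each = 30), ncol = 2),
                matrix(rep(c(0, 1), each = 30), ncol = 2))
  expr2 <- basis_expr(load + matrix(rnorm(120, sd = 0.01), ncol = 2))
  part2 <- tibble::tibble(gene = rownames(expr2),
                          module = rep(c("blue", "brown"), each = 30))
  eg3 <- module_eigengenes(expr2, part2)
  expect_lt(abs(cor(eg3$me[, 1], eg3$me[, 2])), 0.2)
  const <- expr; const["a", ] <- 5
  expect_error(module_eigengenes(const, part), "constant")
})

test_that("eigengene merging iterates to a fixed point", {
  # identical factors merge, orthogonal factors stay apart
  load_dup <- rbind(matrix(rep(c(1, 0), each = 30), ncol = 2),
                    matrix(rep(c(1, 0), each = 30), ncol = 2),
                    matrix(rep(c(0, 1), each = 30), ncol = 2))
  expr <- basis_expr(load_dup + matrix(rnorm(180, sd = 0.01), ncol = 2))
  part <- tibble::tibble(gene = rownames(expr),
                         module = rep(c("blue", "brown", "yellow"), each = 30))
  merged <- merge_close_modules(expr, part, 0.25)
  mods <- unique(merged$module)
  expect_length(mods, 2)
  expect_true(all(merged$module[1:30] == merged$module[31:60]))
  expect_false(merged$module[1] == merged$module[61])
  # a chain a~b, b~c close, a~c distant still collapses after iteration:
  # merging a and b moves the merged eigengene toward c
  # target correlations: cor(a,b) = cor(b,c) = 0.9, cor(a,c) = 0.65
  r_ab <- 0.9; r_bc <- 0.9; r_ac <- 0.65
  l_a <- c(1, 0, 0)
  l_b <- c(r_ab, sqrt(1 - r_ab^2), 0)
  l_c <- c(r_ac, (r_bc - r_ab * r_ac) / l_b[2], 0)
  l_c[3] <- sqrt(1 - sum(l_c[1:2]^2))
  chain_load <- rbind(matrix(l_a, 40, 3, byrow = TRUE),
                      matrix(l_b, 40, 3, byrow = TRUE),
                      matrix(l_c, 40, 3, byrow = TRUE))
  expr3 <- basis_expr(chain_load + matrix(rnorm(360, sd = 0.005), ncol = 3))
  part3 <- tibble::tibble(gene = rownames(expr3),
                          module = rep(c("a", "b", "c"), each = 40))
  eg <- module_eigengenes(expr3, part3)
  dis <- 1 - cor(eg$me)
  expect_lt(dis["a", "b"], 0.25)
  expect_gt(dis["a", "c"], 0.25)
  merged3 <- merge_close_modules(expr3, part3, 0.25)
  expect_length(unique(merged3$module), 1)
})

test_that("planted modules are recovered and recovery survives gene permutation", {
  cfg <- four_module_config(seed = 1)
  ex <- simulate_expression(cfg)
  norm <- normalize_log(ex$counts)
  net <- build_network(norm, top_n = 400, min_module_size = 30)
  truth <- ex$truth$module[match(net$partition$gene, ex$truth$gene)]
  expect_gte(adjusted_rand(net$partition$module, truth), 0.9)
  # permuting gene order changes nothing but labels
  perm <- sample(nrow(norm))
  net2 <- build_network(norm[perm, ], top_n = 400, min_module_size = 30,
                        power = net$power)
  m1 <- net$partition$module[match(net2$partition$gene, net$partition$gene)]
  expect_equal(adjusted_rand(m1, net2$partition$module), 1)
})
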