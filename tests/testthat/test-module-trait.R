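test_that("median dichotomization uses the strict tie rule", {
  expect_equal(sum(dichotomize_me(1:10)), 5)
  expect_equal(dichotomize_me(c(1, 2, 2, 3)), c(FALSE, FALSE, FALSE, TRUE))
  me <- rnorm(12)
  expect_equal(dichotomize_me(me), dichotomize_me(exp(me)))
  expect_error(dichotomize_me(rep(1, 5)), "constant")
  expect_error(dichotomize_me(3), "2 samples")
})

test_that("contingency coefficient reproduces the closed-form 2x2 values", {
  grp <- rep(c("AF", "SR"), each = 5)
  perfect <- contingency_coefficient(rep(c(TRUE, FALSE), each = 5), grp)
  expect_equal(round(perfect$cc, 2), 0.71)
  expect_equal(perfect$chi2, 10)
  one_off <- contingency_coefficient(
    c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE), grp)
  expect_equal(round(one_off$cc, 2), 0.51)
  expect_equal(one_off$chi2, 3.6)
  flat <- contingency_coefficient(c(TRUE, TRUE, FALSE, FALSE, FALSE,
                                    TRUE, TRUE, FALSE, FALSE, FALSE), grp)
  expect_equal(flat$cc, 0)
  expect_warning(zm <- contingency_coefficient(rep(TRUE, 10), grp), "margin")
  expect_equal(zm$cc, 0)
})

test_that("chi-square equals the textbook 2x2 formula and CC is bounded", {
  set.seed(33)
  for (rep in 1:30) {
    x <- sample(c(TRUE, FALSE), 12, replace = TRUE)
    y <- sample(c("a", "b"), 12, replace = TRUE)
    tab <- table(factor(x, c(FALSE, TRUE)), factor(y, c("a", "b")))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    res <- contingency_coefficient(x, y)
    a <- tab[1, 1]; b <- tab[1, 2]; c2 <- tab[2, 1]; d <- tab[2, 2]
    n <- sum(tab)
    chi_text <- n * (a * d - b * c2)^2 /
      (sum(tab[1, ]) * sum(tab[2, ]) * sum(tab[, 1]) * sum(tab[, 2]))
    expect_equal(res$chi2, unname(chi_text))
    expect_lte(res$cc, sqrt(0.5) + 1e-12)
    # symmetry in the two variables and under label swap
    expect_equal(contingency_coefficient(y == "a", x)$cc, res$cc)
    expect_equal(contingency_coefficient(!x, y)$cc, res$cc)
  }
})

test_that("module-trait scoring finds the trait-linked planted module", {
  cfg <- planted_pipeline_config()
  ex <- simulate_expression(cfg)
  norm <- normalize_log(ex$counts)
  net <- build_network(norm, top_n = 500, min_module_size = 30)
  mt <- module_trait_cc(net$eigengenes, ex$metadata)
  trait_genes <- ex$truth$gene[1:100]
  tab <- table(net$partition$module[net$partition$gene %in% trait_genes])
  trait_module <- names(which.max(tab))
  expect_equal(round(mt$cc[mt$module == trait_module], 2), 0.71)
  expect_lt(mt$p[mt$module == trait_module], 0.05)
})

test_that("module membership is the eigengene correlation", {
  s <- sin(seq_len(30)); t2 <- cos(seq_len(30))
  expr <- rbind(a = s + rnorm(30, sd = 1e-3), b = s, c = -s, d = t2)
  colnames(expr) <- paste0("s", 1:30)
  part <- tibble::tibble(gene = c("a", "b", "c", "d"),
                         module = c("blue", "blue", "blue", "brown"))
  # brown needs two genes for an eigengene; duplicate d
  expr <- rbind(expr, e = t2 + rnorm(30, sd = 1e-3))
  part <- dplyr::add_row(part, gene = "e", module = "brown")
  eg <- module_eigengenes(expr, part)
  mm <- module_membership(expr, eg)
  own <- dplyr::semi_join(mm, part, by = c("gene", "module"))
  expect_true(all(abs(abs(own$mm) - 1) < 1e-3))
  me_blue <- eg$me[, "blue"]
  mm_b <- mm$mm[mm$gene == "b" & mm$module == "blue"]
  expect_equal(mm_b, cor(s, me_blue))
  mm_c <- mm$mm[mm$gene == "c" & mm$module == "blue"]
  expect_equal(mm_c, -mm_b)
})

test_that("GS-MM association flags only genuinely coupled modules", {
  cfg <- planted_pipeline_config(seed = 12)
  ex <- simulate_expression(cfg)
  norm <- normalize_log(ex$counts)
  net <- build_network(norm, top_n = 500, min_module_size = 30)
  de <- de_test(ex$counts, ex$metadata)
  mm <- module_membership(net$expr, net$eigengenes)
  gsmm <- gs_mm_association(mm, de, net$partition)
  trait_module <- names(which.max(
    table(net$partition$module[net$partition$gene %in% ex$truth$gene[1:100]])))
  row <- gsmm[gsmm$module == trait_module, ]
  expect_true(row$significant)
  expect_gt(row$r, 0.3)
  # GS exactly linear in MM gives R = 1
  lin <- tibble::tibble(gene = paste0("g", 1:10), module = "blue",
                        mm = seq(0.1, 1, 0.1))
  de_lin <- tibble::tibble(gene = paste0("g", 1:10),
                           gs = 2 * seq(0.1, 1, 0.1) + 1)
  part_lin <- tibble::tibble(gene = paste0("g", 1:10), module = "blue")
  expect_equal(gs_mm_association(lin, de_lin, part_lin)$r, 1)
  # GS decoupled from MM (permuted) is rarely flagged
  set.seed(44)
  flags <- vapply(1:20, function(i) {
    de_perm <- de_lin
    de_perm$gs <- sample(rnorm(10))
    gs_mm_association(lin, de_perm, part_lin)$significant
  }, logical(1))
  expect_gte(mean(!flags), 0.75)
})
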