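# Shared simulation configurations, kept small so the suite stays fast.

null_expr_config <- function(seed = 11, n_genes = 200,
                             n_samples_per_group = 5) {
  sim_config(
    seed = seed, n_genes = n_genes, n_samples_per_group = n_samples_per_group,
    module_spec = data.frame(module_size = integer(),
                             latent_correlation = numeric(),
                             trait_effect = numeric())
  )
}

one_module_config <- function(seed = 31, rho = 0.8) {
  sim_config(
    seed = seed, n_genes = 500, n_samples_per_group = 10,
    module_spec = data.frame(module_size = 100, latent_correlation = rho,
                             trait_effect = 0)
  )
}

four_module_config <- function(seed = 1) {
  sim_config(
    seed = seed, n_genes = 400, n_samples_per_group = 5,
    module_spec = data.frame(module_size = c(100, 100, 100, 100),
                             latent_correlation = 0.8,
                             trait_effect = c(2, 0, 0, 0))
  )
}

# The full integrative scenario: a trait-linked module whose first genes are
# also planted differentially expressed and GWAS-causal in both sets.
planted_pipeline_config <- function(seed = 5) {
  sim_config(
    seed = seed, n_genes = 500, n_samples_per_group = 5,
    module_spec = data.frame(module_size = c(100, 100),
                             latent_correlation = c(0.85, 0.85),
                             trait_effect = c(3, 0)),
    de_spec = data.frame(gene = 1:5, log2fc = 4),
    causal_genes = data.frame(gene = 1:5, p_scale = 1e-8)
  )
}
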