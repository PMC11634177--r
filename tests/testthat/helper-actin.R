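# Shared fixtures. Everything is generated in code; the expensive
# parameter-recovery benchmark is trained once per test run and cached.

tiny_config <- function(d = 32, n_blocks = 2) {
  actin_config(d = d, gat_heads = 4, n_gat_stages = 2, if_heads = 4,
               n_blocks = n_blocks, ffn_hidden = 2 * d)
}

tiny_model <- function(seed = 3, d = 32, n_blocks = 2) {
  new_cell_line_model("TINY", tiny_config(d, n_blocks), seed = seed)
}

# small random embedding table over the synthetic gene ids
random_embeddings <- function(n_genes, dim = 128, seed = 11) {
  set.seed(seed)
  as_gene_embedding(
    matrix(rnorm(n_genes * dim), n_genes, dim,
           dimnames = list(synth_gene_ids(n_genes), NULL)),
    source = "loaded"
  )
}

# random connected molecular graph via the generator
random_graphs <- function(n, seed = 5) {
  generate_molecules(n, synth_config(seed = seed))$graph
}

# The repository's parameter-recovery benchmark: study conditions from
# benchmark_synth_config() (200 drugs, 100 genes, S -> g0001..g0020 with
# beta 2.5, noise sd 0.3, generator seed 42), reduced model width d = 64
# (d_k = 16), 2 interfusion blocks, 2 GAT stages, batch 1000, Adam lr
# 1e-3, 40 epochs, 80/20 instance split. Trained once and memoised.
benchmark_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    scfg <- benchmark_synth_config()
    mols <- generate_molecules(scfg$n_drugs, scfg)
    pert <- generate_perturbations(mols, scfg$n_genes, scfg$effects,
                                   scfg$noise_sd, seed = scfg$seed,
                                   cell_line = "SYN1")
    ppi <- generate_ppi(scfg$n_genes, mean_degree = 6, seed = scfg$seed)
    emb <- node2vec_embed(ppi, dim = 128, walk_length = 20,
                          walks_per_node = 5, epochs = 3, seed = scfg$seed)
    mc <- actin_config(d = 64, gat_heads = 4, n_gat_stages = 2,
                       if_heads = 4, n_blocks = 2, ffn_hidden = 256)
    tc <- train_config(batch_size = 1000, lr = 1e-3, epochs = 25,
                       split = c(train = 0.8, test = 0.2), seed = 7)
    res <- train_cell_line(pert, emb, mc, tc)
    cache <<- list(synth = scfg, molecules = mols, perturbations = pert,
                   embeddings = emb, model = res$model,
                   history = res$history)
    cache
  }
})

# Two-cell-line family over a shared molecule set: line A plants sulfur,
# line B plants phosphorus, on disjoint gene modules. Reduced sizes keep
# the disparity analysis affordable.
family_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    scfg <- synth_config(n_drugs = 120, n_genes = 60,
                         element_prevalence = c(S = 0.3, P = 0.3),
                         noise_sd = 0.3, seed = 101)
    mols <- generate_molecules(scfg$n_drugs, scfg)
    ppi <- generate_ppi(scfg$n_genes, mean_degree = 6, seed = 101)
    emb <- node2vec_embed(ppi, dim = 128, walk_length = 20,
                          walks_per_node = 5, epochs = 3, seed = 101)
    eff <- list(
      A = list(planted_effect("S", synth_gene_ids(60)[1:12], 2.5, 1)),
      B = list(planted_effect("P", synth_gene_ids(60)[13:24], 2.5, 1))
    )
    mc <- actin_config(d = 64, gat_heads = 4, n_gat_stages = 2,
                       if_heads = 4, n_blocks = 2, ffn_hidden = 256)
    models <- lapply(names(eff), function(cl) {
      pert <- generate_perturbations(mols, scfg$n_genes, eff[[cl]],
                                     scfg$noise_sd, seed = 200 + match(cl, names(eff)),
                                     cell_line = cl)
      tc <- train_config(batch_size = 1000, lr = 1e-3, epochs = 25,
                         split = c(train = 0.8, test = 0.2), seed = 7)
      train_cell_line(pert, emb, mc, tc)$model
    })
    names(models) <- names(eff)
    cache <<- list(models = models, molecules = mols,
                   planted = c(A = "S", B = "P"))
    cache
  }
})
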