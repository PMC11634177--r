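test_that("molecule generation is deterministic and respects edge cases", {
  cfg <- synth_config(seed = 5)
  expect_equal(nrow(generate_molecules(0, cfg)), 0L)
  a <- generate_molecules(30, cfg)
  b <- generate_molecules(30, cfg)
  expect_identical(a$smiles, b$smiles)
})

test_that("generated molecules are connected, valence-capped and parseable", {
  caps <- c(C = 4, N = 3, O = 2, Cl = 1, Ca = 2, S = 2, F = 1, Br = 1,
            I = 1, P = 4, Au = 1, B = 3, Si = 4, Hg = 1)
  mols <- generate_molecules(50, synth_config(seed = 3))
  for (g in mols$graph) {
    deg <- tabulate(as.vector(g$edges), nbins = length(g$elements))
    expect_true(all(deg <= caps[g$elements]))
    expect_true(graphs_isomorphic(parse_smiles(g$smiles), g))
  }
})

test_that("element composition follows the prevalence map", {
  mols <- generate_molecules(1000, synth_config(element_prevalence = c(S = 0.3),
                                                seed = 1))
  frac_s <- mean(vapply(mols$graph, function(g) "S" %in% g$elements, logical(1)))
  expect_gt(frac_s, 0.25)
  expect_lt(frac_s, 0.35)
  expect_error(synth_config(element_prevalence = c(S = 1.7)), "\\[0, 1\\]")
  expect_error(synth_config(element_prevalence = c(Xx = 0.5)), "vocabulary")
})

test_that("PPI generation yields a simple connected graph at the target degree", {
  expect_error(generate_ppi(1), "at least 2")
  e2 <- generate_ppi(2, mean_degree = 1, seed = 1)
  expect_equal(nrow(e2), 1L)

  ppi <- generate_ppi(500, mean_degree = 6, seed = 2)
  expect_false(any(ppi$gene_a == ppi$gene_b))
  expect_false(anyDuplicated(paste(ppi$gene_a, ppi$gene_b)) > 0)
  mean_deg <- 2 * nrow(ppi) / 500
  expect_gt(mean_deg, 5)
  expect_lt(mean_deg, 7)
  ig <- igraph::graph_from_data_frame(ppi, directed = FALSE)
  expect_true(igraph::is_connected(ig))
})

test_that("perturbations follow the additive planted-effect model", {
  cfg <- synth_config(seed = 21)
  mols <- generate_molecules(40, cfg)
  eff <- list(planted_effect("S", c("g0001", "g0002"), beta = 2, direction = 1))
  pert <- generate_perturbations(mols, 10, eff, noise_sd = 0, seed = 1)
  expect_equal(nrow(pert), 40 * 10)

  has_s <- vapply(mols$graph, function(g) "S" %in% g$elements, logical(1))
  names(has_s) <- mols$drug_id
  on_target <- pert$gene_id %in% c("g0001", "g0002")
  carrier <- has_s[pert$drug_id]
  expect_true(all(pert$logFC[carrier & on_target] == 2))
  expect_true(all(pert$logFC[!(carrier & on_target)] == 0))
})

test_that("noise has the configured spread on off-target genes", {
  cfg <- synth_config(seed = 8)
  mols <- generate_molecules(200, cfg)
  eff <- list(planted_effect("S", "g0001", beta = 2.5, direction = 1))
  pert <- generate_perturbations(mols, 20, eff, noise_sd = 0.3, seed = 4)
  off <- pert$logFC[pert$gene_id != "g0001"]
  expect_gt(sd(off), 0.27)
  expect_lt(sd(off), 0.33)
})

test_that("noise-free labels equal the planted labels", {
  cfg <- synth_config(seed = 13)
  mols <- generate_molecules(30, cfg)
  eff <- list(planted_effect("O", c("g0003", "g0004"), beta = 1.5,
                             direction = -1))
  pert <- generate_perturbations(mols, 6, eff, noise_sd = 0, seed = 1)
  has_o <- vapply(mols$graph, function(g) "O" %in% g$elements, logical(1))
  names(has_o) <- mols$drug_id
  planted <- ifelse(has_o[pert$drug_id] & pert$gene_id %in% c("g0003", "g0004"),
                    "Down", "None")
  expect_equal(as.character(expr_label(pert$logFC)), unname(planted))
})

test_that("planted-effect validation rejects bad configurations", {
  expect_error(planted_effect("Zz", "g0001", 1), "vocabulary")
  expect_error(planted_effect("S", character(), 1), "non-empty")
  expect_error(planted_effect("S", "g0001", -2), "beta")
  expect_error(planted_effect("S", "g0001", 1, direction = 0), "direction")
  expect_error(synth_config(n_genes = 5,
                            effects = list(planted_effect("S", "g0009", 1))),
               "beyond n_genes")
})
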