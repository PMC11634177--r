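test_that("pair building preserves counts and validates inputs", {
  cfg <- synth_config(seed = 17)
  mols <- generate_molecules(3, cfg)
  pert <- generate_perturbations(mols, 5, list(), noise_sd = 0.2, seed = 2)
  emb <- random_embeddings(5)
  built <- build_pairs(pert, emb)
  expect_equal(nrow(built$samples), 15L)
  expect_equal(built$samples$target, step_function(built$samples$logFC))
  expect_equal(length(built$graphs), 3L)

  z <- pert[1, ]; z$logFC <- 0
  expect_equal(build_pairs(z, emb)$samples$target, 0)

  bad <- pert; bad$gene_id[1] <- "g9999"
  expect_error(build_pairs(bad, emb), "g9999")
  badsm <- pert; badsm$smiles[badsm$drug_id == "d0002"] <- "C1CC"
  expect_error(build_pairs(badsm, emb), "d0002")
})

test_that("instance splitting uses floor sizes and is seed-deterministic", {
  ids <- sprintf("i%03d", 1:492)
  f <- split_instances(ids, c(train = 0.8, test = 0.2), seed = 3)
  expect_equal(sum(f == "train"), 393L)
  expect_equal(sum(f == "test"), 99L)

  f3 <- split_instances(sprintf("i%02d", 1:10), c(train = 0.6, val = 0.2,
                                                  test = 0.2), seed = 1)
  expect_equal(unname(table(f3)[c("train", "val", "test")]), c(6L, 2L, 2L),
               ignore_attr = TRUE)

  expect_identical(split_instances(ids, seed = 9), split_instances(ids, seed = 9))
  expect_false(identical(split_instances(ids, seed = 9),
                         split_instances(ids, seed = 10)))
  expect_error(split_instances(character()), "no instances")
  expect_error(split_instances("a", c(train = 0.5, test = 0.5)), "too few")
})

test_that("smooth-L1 matches its closed form and its gradient", {
  expect_equal(smooth_l1(1.3, 1.3), 0)
  expect_equal(smooth_l1(1, 0.5), 0.125)   # 0.5 * 0.5^2
  expect_equal(smooth_l1(2.5, 0.5), 1.5)   # |2| - 0.5
  expect_equal(smooth_l1(c(1, 2.5), c(0.5, 0.5)), (0.125 + 1.5) / 2)
  expect_error(smooth_l1(1, 1, beta = 0), "beta")
  expect_error(smooth_l1(NA, 1), "finite")

  # numerical vs analytic gradient at both branches
  for (pred0 in c(0.3, 1.9)) {
    tape <- actin:::ag_tape()
    p <- actin:::ag_param(tape, matrix(pred0))
    loss <- actin:::ag_smooth_l1(tape, p, matrix(0), 1)
    actin:::ag_backward(tape, loss)
    eps <- 1e-7
    num <- (smooth_l1(pred0 + eps, 0) - smooth_l1(pred0 - eps, 0)) / (2 * eps)
    expect_equal(p$grad[1, 1], num, tolerance = 1e-5)
  }
})

test_that("training learns a noise-free planted dataset and is reproducible", {
  cfg <- synth_config(n_drugs = 24, n_genes = 8, seed = 5,
                      element_prevalence = c(S = 0.5))
  mols <- generate_molecules(cfg$n_drugs, cfg)
  eff <- list(planted_effect("S", c("g0001", "g0002"), beta = 2.5, direction = 1))
  pert <- generate_perturbations(mols, cfg$n_genes, eff, noise_sd = 0, seed = 1)
  emb <- random_embeddings(cfg$n_genes, seed = 2)
  mc <- tiny_config()
  tc <- train_config(batch_size = 64, lr = 3e-3, epochs = 8,
                     split = c(train = 0.8, test = 0.2), seed = 4)
  res <- train_cell_line(pert, emb, mc, tc)
  h <- res$history
  expect_lt(tail(h$train_loss, 1), h$train_loss[1])
  expect_true(res$model$trained)
  expect_equal(nrow(h), 8L)

  # bit-identical rerun under the same seed
  res2 <- train_cell_line(pert, emb, mc, tc)
  expect_identical(res$model$params, res2$model$params)
  expect_equal(tail(res2$history$train_loss, 1), tail(h$train_loss, 1))
})

test_that("degenerate batching and fold bookkeeping behave", {
  cfg <- synth_config(n_drugs = 6, n_genes = 4, seed = 6)
  mols <- generate_molecules(cfg$n_drugs, cfg)
  pert <- generate_perturbations(mols, cfg$n_genes, list(), 0.1, seed = 3)
  emb <- random_embeddings(cfg$n_genes)
  tc <- train_config(batch_size = 5000, lr = 1e-3, epochs = 2,
                     split = c(train = 0.5, val = 0.25, test = 0.25), seed = 2)
  res <- train_cell_line(pert, emb, tiny_config(), tc)
  expect_equal(sort(unique(res$model$split)), c("test", "train", "val"))
  expect_false(any(is.na(res$history$val_loss)))

  mixed <- rbind(pert, transform(pert[1, ], cell_line = "OTHER"))
  expect_error(train_cell_line(mixed, emb, tiny_config(), tc), "cell lines")
})

test_that("validation-based early stopping restores the best parameters", {
  cfg <- synth_config(n_drugs = 20, n_genes = 6, seed = 12,
                      element_prevalence = c(S = 0.5))
  mols <- generate_molecules(cfg$n_drugs, cfg)
  eff <- list(planted_effect("S", "g0001", beta = 2, direction = 1))
  pert <- generate_perturbations(mols, cfg$n_genes, eff, noise_sd = 0.1, seed = 5)
  emb <- random_embeddings(cfg$n_genes, seed = 8)
  tc <- train_config(batch_size = 64, lr = 3e-3, epochs = 6, patience = 2,
                     split = c(train = 0.6, val = 0.2, test = 0.2), seed = 3)
  res <- train_cell_line(pert, emb, tiny_config(), tc)
  h <- res$history
  # the restored parameters reproduce the best recorded validation loss
  va <- names(res$model$split)[res$model$split == "val"]
  built <- build_pairs(pert[pert$drug_id %in% va, ], emb)
  vp <- predict_pairs(res$model, built$samples, built$graphs, emb)
  expect_equal(smooth_l1(vp, built$samples$target), min(h$val_loss),
               tolerance = 1e-10)
})
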