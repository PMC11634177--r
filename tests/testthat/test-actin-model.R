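# Layer-level contracts of the network, including independent brute-force
# oracles for the two attention mechanisms.

test_that("atom embedding is a shared per-element map", {
  m <- tiny_model()
  g <- parse_smiles("CCOC")
  E <- embed_atoms(one_hot_atoms(g), m)
  expect_equal(dim(E), c(4L, 32L))
  expect_equal(E[1, ], E[2, ])  # both carbons
  expect_equal(E[1, ], E[4, ])
  expect_false(isTRUE(all.equal(E[1, ], E[3, ])))

  zero <- list("atom.W" = matrix(0, 14, 32), "atom.b" = matrix(0, 1, 32))
  expect_equal(embed_atoms(one_hot_atoms(g), zero), matrix(0, 4, 32))
  expect_error(embed_atoms(matrix(1, 2, 13), m), "14 columns")
})

test_that("GATv2 attention is a proper softmax over neighbourhoods", {
  params <- gatv2_params(8, heads = 3, head_dim = 4, seed = 2)
  # single node: only the self-loop, so alpha = 1
  r1 <- gatv2_layer(matrix(rnorm(8), 1, 8), matrix(integer(), 0, 2), params)
  for (att in r1$attention) expect_equal(att$alpha, 1)

  set.seed(9)
  for (rep in 1:5) {
    n <- sample(3:7, 1)
    edges <- cbind(seq_len(n - 1), 2:n)  # path graph
    X <- matrix(rnorm(n * 8), n, 8)
    r <- gatv2_layer(X, edges, params)
    for (att in r$attention) {
      sums <- tapply(att$alpha, att$dst, sum)
      expect_equal(as.vector(sums), rep(1, n), tolerance = 1e-6)
      expect_true(all(att$alpha >= 0))
    }
  }
})

test_that("GATv2 forward equals a dense brute-force reimplementation", {
  # oracle: score every ordered pair, mask non-neighbours, softmax, sum
  dense_gatv2 <- function(X, edges, params, slope) {
    n <- nrow(X)
    A <- diag(n) > 0
    for (k in seq_len(nrow(edges))) {
      A[edges[k, 1], edges[k, 2]] <- TRUE
      A[edges[k, 2], edges[k, 1]] <- TRUE
    }
    outs <- lapply(params$heads, function(ph) {
      out <- matrix(0, n, ncol(ph$Wl))
      for (i in seq_len(n)) {
        sc <- rep(-Inf, n)
        for (j in which(A[i, ])) {
          z <- X[i, ] %*% ph$Wl + X[j, ] %*% ph$Wr
          z <- ifelse(z > 0, z, slope * z)
          sc[j] <- z %*% ph$a
        }
        al <- exp(sc - max(sc, na.rm = TRUE))
        al[!A[i, ]] <- 0
        al <- al / sum(al)
        for (j in which(A[i, ])) out[i, ] <- out[i, ] + al[j] * (X[j, ] %*% ph$Wr)
      }
      out
    })
    do.call(cbind, outs) +
      matrix(params$b, n, length(params$heads) * ncol(params$heads[[1]]$Wl),
             byrow = TRUE)
  }
  set.seed(4)
  params <- gatv2_params(6, heads = 2, head_dim = 5, seed = 8)
  X <- matrix(rnorm(30), 5, 6)
  edges <- cbind(1:4, 2:5)  # 5-node path
  got <- gatv2_layer(X, edges, params, leaky_slope = 0.2)
  expect_equal(got$features, dense_gatv2(X, edges, params, 0.2),
               tolerance = 1e-6)
})

test_that("TopK pooling keeps the right nodes and breaks ties by index", {
  set.seed(5)
  X <- matrix(rnorm(80), 10, 8)
  edges <- cbind(1:9, 2:10)
  prm <- list(p = matrix(rnorm(8), ncol = 1))
  full <- topk_pool(X, edges, prm, ratio = 1)
  expect_equal(full$kept, 1:10)
  r <- topk_pool(X, edges, prm, ratio = 0.8)
  expect_equal(length(r$kept), 8L)  # ceiling(0.8 * 10)
  # gating: kept features are the originals scaled by tanh(score)
  score <- as.vector(X %*% prm$p) / sqrt(sum(prm$p^2))
  expect_equal(r$features, X[r$kept, ] * tanh(score[r$kept]))

  # equal scores -> lowest indices kept
  Xeq <- matrix(1, 6, 8)
  req <- topk_pool(Xeq, cbind(1:5, 2:6), prm, ratio = 0.5)
  expect_equal(req$kept, 1:3)
})

test_that("drug encoding is permutation invariant and well shaped", {
  m <- tiny_model(seed = 6)
  g <- parse_smiles("CC(N)C(=O)OCC1CC1S")
  D <- encode_drug(g, m)
  expect_length(D, 32L)
  set.seed(31)
  for (k in 1:50) {
    perm <- sample(length(g$elements))
    inv <- order(perm)  # inv[old] = new position
    gp <- molecular_graph(g$elements[perm],
                          matrix(inv[as.vector(g$edges)], ncol = 2))
    expect_equal(encode_drug(gp, m), D, tolerance = 1e-6)
  }
})

test_that("single-atom molecules give equal mean and max readouts", {
  cfg <- tiny_config()
  m <- tiny_model(seed = 9)
  bg <- actin:::batch_graphs(list(parse_smiles("[Ca]")))
  tape <- actin:::ag_tape()
  pn <- actin:::.params_as_nodes(tape, m$params, trainable = FALSE)
  H <- actin:::.fwd_linear(tape, actin:::ag_const(tape, bg$onehot),
                           pn[["atom.W"]], pn[["atom.b"]])
  gat <- actin:::.fwd_gat(tape, pn, 1, H, bg$edges, 1L, cfg)
  r <- actin:::.fwd_readout(tape, gat$H, bg$gid, 1L)
  v <- actin:::ag_value(r)
  expect_equal(v[, 1:32], v[, 33:64])  # mean == max for n = 1
})

test_that("gene projection is a deterministic two-layer map", {
  m <- tiny_model(seed = 12)
  x <- rnorm(128)
  G <- project_gene(x, m)
  expect_length(G, 32L)
  expect_equal(project_gene(x, m), G)
  expect_error(project_gene(rnorm(64), m), "length 128")
  zero <- m
  zero$params[["geneproj.W1"]][] <- 0
  zero$params[["geneproj.W2"]][] <- 0
  expect_equal(project_gene(x, zero), rep(0, 32))
})

test_that("interfusion attention rows are stochastic and the residual path is exact", {
  m <- tiny_model(seed = 20)
  X <- matrix(rnorm(64), 2, 32)
  r <- interfusion_block(X, m, block = 1)
  for (A in r$attention) {
    expect_equal(unname(rowSums(A)), c(1, 1), tolerance = 1e-6)
    expect_true(all(A >= 0))
  }
  # zero both sublayer output maps -> identity block
  mz <- m
  mz$params[["blk1.Wo"]][] <- 0
  mz$params[["blk1.ffn.W2"]][] <- 0
  mz$params[["blk1.ffn.b2"]][] <- 0
  rz <- interfusion_block(X, mz, block = 1)
  expect_equal(rz$X, X)
})

test_that("interfusion block equals a step-by-step scalar oracle", {
  # independent reimplementation straight from the printed equations,
  # using explicit 2x2 softmax instead of the package's logistic form
  oracle_block <- function(X, p, i, heads, dk) {
    ln <- function(M, g, b) {
      t(apply(M, 1, function(r) {
        (r - mean(r)) / sqrt(mean((r - mean(r))^2) + 1e-5)
      })) * matrix(g, nrow(M), length(g), byrow = TRUE) +
        matrix(b, nrow(M), length(b), byrow = TRUE)
    }
    Xn <- ln(X, p[[sprintf("blk%d.ln1.g", i)]], p[[sprintf("blk%d.ln1.b", i)]])
    O <- NULL
    for (h in seq_len(heads)) {
      Q <- Xn %*% p[[sprintf("blk%d.h%d.Wq", i, h)]]
      K <- Xn %*% p[[sprintf("blk%d.h%d.Wk", i, h)]]
      V <- Xn %*% p[[sprintf("blk%d.h%d.Wv", i, h)]]
      S <- Q %*% t(K) / sqrt(dk)
      A <- t(apply(S, 1, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
      O <- cbind(O, A %*% V)
    }
    X1 <- X + O %*% p[[sprintf("blk%d.Wo", i)]]
    X1n <- ln(X1, p[[sprintf("blk%d.ln2.g", i)]], p[[sprintf("blk%d.ln2.b", i)]])
    H <- pmax(X1n %*% p[[sprintf("blk%d.ffn.W1", i)]] +
                matrix(p[[sprintf("blk%d.ffn.b1", i)]], 2,
                       length(p[[sprintf("blk%d.ffn.b1", i)]]), byrow = TRUE), 0)
    X1 + H %*% p[[sprintf("blk%d.ffn.W2", i)]] +
      matrix(p[[sprintf("blk%d.ffn.b2", i)]], 2,
             length(p[[sprintf("blk%d.ffn.b2", i)]]), byrow = TRUE)
  }
  m <- tiny_model(seed = 33)
  set.seed(14)
  X <- matrix(rnorm(64, sd = 2), 2, 32)
  got <- interfusion_block(X, m, block = 2)$X
  want <- oracle_block(X, m$params, 2, heads = 4, dk = 8)
  expect_equal(got, want, tolerance = 1e-6)
})

test_that("predicted scores are bounded, deterministic and order-sensitive", {
  m <- tiny_model(seed = 40)
  set.seed(2)
  for (k in 1:20) {
    G <- rnorm(32, sd = 3)
    D <- rnorm(32, sd = 3)
    s <- predict_score(G, D, m)
    expect_lt(abs(s), 1)
    expect_identical(predict_score(G, D, m), s)
  }
  G <- rnorm(32); D <- rnorm(32)
  expect_false(isTRUE(all.equal(predict_score(G, D, m),
                                predict_score(D, G, m))))
})

test_that("checkpoints round-trip through JSON with hash validation", {
  m <- tiny_model(seed = 77)
  tmp <- withr::local_tempfile(fileext = ".json")
  save_cell_line_model(m, tmp)
  back <- load_cell_line_model(tmp)
  expect_equal(back$params, m$params)
  expect_equal(back$config_hash, m$config_hash)
  expect_equal(unclass(back$config), unclass(m$config))
  # same inputs -> same predictions
  G <- rnorm(32); D <- rnorm(32)
  expect_equal(predict_score(G, D, back), predict_score(G, D, m))
})
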