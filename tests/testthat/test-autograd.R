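# Finite-difference validation of the reverse-mode tape. Each case builds
# a scalar function from tape ops and compares every input gradient to a
# central difference.

num_grad <- function(f, x, eps = 1e-6) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

check_op <- function(build, x0, tol = 1e-5) {
  f <- function(x) {
    tape <- ag_tape()
    actin:::ag_value(build(tape, actin:::ag_param(tape, x)))[1, 1]
  }
  tape <- ag_tape()
  xn <- actin:::ag_param(tape, x0)
  out <- build(tape, xn)
  actin:::ag_backward(tape, out)
  expect_equal(xn$grad, num_grad(f, x0), tolerance = tol,
               ignore_attr = TRUE)
}

test_that("core tape operations match finite differences", {
  set.seed(42)
  x0 <- matrix(rnorm(12), 3, 4)
  W <- matrix(rnorm(8), 4, 2)
  ag <- function(nm) get(nm, asNamespace("actin"))

  check_op(function(t, x) ag("ag_sum")(t, ag("ag_mm")(t, x, ag("ag_const")(t, W))), x0)
  check_op(function(t, x) ag("ag_mean")(t, ag("ag_tanh")(t, x)), x0)
  check_op(function(t, x) ag("ag_sum")(t, ag("ag_sigmoid")(t, x)), x0)
  check_op(function(t, x) ag("ag_sum")(t, ag("ag_leaky_relu")(t, x, 0.2)), x0)
  check_op(function(t, x) ag("ag_sum")(t, ag("ag_mul")(t, x, x)), x0)
  check_op(function(t, x) ag("ag_sum")(t, ag("ag_rowsums")(t, ag("ag_exp")(t, x))), x0)
  check_op(function(t, x) ag("ag_sum")(t, ag("ag_powc")(t, ag("ag_mul")(t, x, x), 0.5)),
           abs(x0) + 0.5)
  check_op(function(t, x) {
    g1 <- ag("ag_gather")(t, x, c(1L, 1L, 3L, 2L))
    ag("ag_sum")(t, ag("ag_scatter_add")(t, g1, c(1L, 2L, 2L, 1L), 2L))
  }, x0)
  check_op(function(t, x) {
    ag("ag_sum")(t, ag("ag_cbind")(t, ag("ag_relu")(t, x), ag("ag_neg")(t, x)))
  }, x0 + 0.01)
})

test_that("grouped softmax, max and layer norm match finite differences", {
  set.seed(7)
  ag <- function(nm) get(nm, asNamespace("actin"))
  s0 <- matrix(rnorm(6), ncol = 1)
  grp <- factor(c(1, 1, 2, 2, 2, 3))
  wvec <- matrix(rnorm(6), ncol = 1)
  check_op(function(t, x) {
    a <- ag("ag_group_softmax")(t, x, grp)
    ag("ag_sum")(t, ag("ag_mul")(t, a, ag("ag_const")(t, wvec)))
  }, s0)

  x0 <- matrix(rnorm(15), 5, 3)
  check_op(function(t, x) {
    ag("ag_sum")(t, ag("ag_group_max")(t, x, c(1L, 1L, 2L, 2L, 2L), 2L))
  }, x0)

  gain <- matrix(runif(3, 0.5, 1.5), 1)
  bias <- matrix(rnorm(3), 1)
  check_op(function(t, x) {
    ag("ag_sum")(t, ag("ag_tanh")(t, ag("ag_layernorm")(
      t, x, ag("ag_const")(t, gain), ag("ag_const")(t, bias))))
  }, x0, tol = 1e-4)
})

test_that("smooth-L1 node and column broadcasts match finite differences", {
  set.seed(3)
  ag <- function(nm) get(nm, asNamespace("actin"))
  target <- matrix(rnorm(5), ncol = 1)
  p0 <- matrix(rnorm(5, sd = 2), ncol = 1)
  check_op(function(t, x) ag("ag_smooth_l1")(t, x, target, 1), p0)
  check_op(function(t, x) ag("ag_smooth_l1")(t, x, target, 0.4), p0)

  x0 <- matrix(rnorm(12), 4, 3)
  v <- matrix(rnorm(4), ncol = 1)
  check_op(function(t, x) {
    ag("ag_sum")(t, ag("ag_mul")(t, x, ag("ag_param")(t, v)))
  }, x0)
  # bias broadcast over rows
  b <- matrix(rnorm(3), 1)
  check_op(function(t, x) {
    ag("ag_sum")(t, ag("ag_tanh")(t, ag("ag_add")(t, x, ag("ag_const")(t, b))))
  }, x0)
})

test_that("gradients flow through the full network to every parameter", {
  set.seed(11)
  cfg <- tiny_config()
  m <- tiny_model(seed = 2)
  graphs <- list(parse_smiles("CCO"), parse_smiles("c1ccccc1"),
                 parse_smiles("C"))
  bg <- actin:::batch_graphs(graphs)
  gene_mat <- matrix(rnorm(3 * 128), 3, 128)
  target <- matrix(c(0.3, -0.6, 0.1), ncol = 1)
  run <- function(params) {
    tape <- ag_tape()
    pn <- lapply(params, function(p) actin:::ag_param(tape, p))
    s <- actin:::.fwd_actin(tape, pn, cfg, bg, gene_mat, c(1L, 2L, 3L))
    list(tape = tape, pn = pn,
         loss = actin:::ag_smooth_l1(tape, s, target))
  }
  r <- run(m$params)
  actin:::ag_backward(r$tape, r$loss)
  expect_true(all(vapply(r$pn, function(nd) !is.null(nd$grad), logical(1))))

  eps <- 1e-6
  for (nm in c("atom.W", "gat1.h2.a", "topk2.p", "geneproj.W1",
               "blk1.h3.Wk", "blk2.Wo", "blk2.ffn.W1", "head.W2")) {
    set.seed(match(nm, names(m$params)))
    ij <- arrayInd(sample(length(m$params[[nm]]), 1), dim(m$params[[nm]]))
    p2 <- m$params
    p2[[nm]][ij] <- p2[[nm]][ij] + eps
    lp <- actin:::ag_value(run(p2)$loss)[1, 1]
    p2[[nm]][ij] <- p2[[nm]][ij] - 2 * eps
    lm <- actin:::ag_value(run(p2)$loss)[1, 1]
    expect_equal(r$pn[[nm]]$grad[ij], (lp - lm) / (2 * eps),
                 tolerance = 1e-3, info = nm)
  }
})
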