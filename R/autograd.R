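# Minimal reverse-mode automatic differentiation over dense matrices.
#
# The network in this package is small but structurally irregular (graph
# attention with per-node softmax, pooling with data-dependent selection,
# layer norm, a two-token transformer), so gradients are computed with a
# tape: every operation records its inputs and a backward closure, and
# ag_backward() replays the tape in reverse creation order. All values are
# base R matrices; operations are vectorized across whole mini-batches, so
# tape overhead is negligible relative to the matrix arithmetic.
#
# Every op's gradient is validated against central finite differences in
# the test suite.

ag_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  t
}

.ag_new <- function(tape, value, parents = list(), backward = NULL,
                    requires = FALSE) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$backward <- backward
  nd$requires <- requires ||
    any(vapply(parents, function(p) p$requires, logical(1)))
  nd$grad <- NULL
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) {
    length(tape$nodes) <- 2L * length(tape$nodes)
  }
  tape$nodes[[tape$n]] <- nd
  nd$id <- tape$n
  nd
}

.ag_acc <- function(nd, g) {
  if (nd$requires) {
    nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
  }
  invisible(NULL)
}

#' @keywords internal
ag_const <- function(tape, value) {
  .ag_new(tape, as.matrix(value))
}

#' @keywords internal
ag_param <- function(tape, value) {
  .ag_new(tape, as.matrix(value), requires = TRUE)
}

#' @keywords internal
ag_value <- function(nd) nd$value

# Run the backward pass from scalar (or any) node `out`.
ag_backward <- function(tape, out, seed_grad = NULL) {
  if (is.null(seed_grad)) {
    seed_grad <- matrix(1, nrow(out$value), ncol(out$value))
  }
  out$grad <- seed_grad
  for (id in seq(out$id, 1L)) {
    nd <- tape$nodes[[id]]
    if (!is.null(nd$grad) && !is.null(nd$backward) && nd$requires) {
      nd$backward(nd$grad)
    }
  }
  invisible(NULL)
}

# ---- arithmetic -----------------------------------------------------------

# a + b; b may be a node of equal shape, a 1 x ncol(a) bias node (broadcast
# over rows), or a plain numeric scalar constant.
ag_add <- function(tape, a, b) {
  if (is.numeric(b) && length(b) == 1L) {
    return(.ag_new(tape, a$value + b, list(a),
                   backward = function(g) .ag_acc(a, g)))
  }
  if (nrow(b$value) == 1L && nrow(a$value) > 1L) {
    val <- a$value + matrix(b$value, nrow(a$value), ncol(a$value), byrow = TRUE)
    return(.ag_new(tape, val, list(a, b), backward = function(g) {
      .ag_acc(a, g)
      .ag_acc(b, matrix(colSums(g), 1L))
    }))
  }
  .ag_new(tape, a$value + b$value, list(a, b), backward = function(g) {
    .ag_acc(a, g); .ag_acc(b, g)
  })
}

ag_neg <- function(tape, a) {
  .ag_new(tape, -a$value, list(a), backward = function(g) .ag_acc(a, -g))
}

ag_sub <- function(tape, a, b) ag_add(tape, a, ag_neg(tape, b))

# elementwise product; b may be equal-shape, an n x 1 column node
# (broadcast over columns), a 1 x 1 scalar node, or a plain numeric
# constant (scalar or matrix).
ag_mul <- function(tape, a, b) {
  if (is.numeric(b)) {
    bb <- if (length(b) == 1L) b else as.matrix(b)
    if (is.matrix(bb) && ncol(bb) == 1L && ncol(a$value) > 1L) {
      bb <- as.vector(bb)  # column broadcast
    }
    return(.ag_new(tape, a$value * bb, list(a),
                   backward = function(g) .ag_acc(a, g * bb)))
  }
  if (all(dim(b$value) == c(1L, 1L)) && !all(dim(a$value) == c(1L, 1L))) {
    k <- b$value[1, 1]
    return(.ag_new(tape, a$value * k, list(a, b), backward = function(g) {
      .ag_acc(a, g * k)
      .ag_acc(b, matrix(sum(g * a$value), 1L, 1L))
    }))
  }
  if (ncol(b$value) == 1L && ncol(a$value) > 1L) {
    v <- as.vector(b$value)
    return(.ag_new(tape, a$value * v, list(a, b), backward = function(g) {
      .ag_acc(a, g * v)
      .ag_acc(b, matrix(rowSums(g * a$value), ncol = 1L))
    }))
  }
  .ag_new(tape, a$value * b$value, list(a, b), backward = function(g) {
    .ag_acc(a, g * b$value); .ag_acc(b, g * a$value)
  })
}

ag_mm <- function(tape, a, b) {
  .ag_new(tape, a$value %*% b$value, list(a, b), backward = function(g) {
    .ag_acc(a, g %*% t(b$value))
    .ag_acc(b, t(a$value) %*% g)
  })
}

ag_powc <- function(tape, a, k) {
  val <- a$value^k
  .ag_new(tape, val, list(a),
          backward = function(g) .ag_acc(a, g * k * a$value^(k - 1)))
}

# ---- elementwise nonlinearities ------------------------------------------

ag_tanh <- function(tape, a) {
  y <- tanh(a$value)
  .ag_new(tape, y, list(a), backward = function(g) .ag_acc(a, g * (1 - y^2)))
}

ag_sigmoid <- function(tape, a) {
  y <- 1 / (1 + exp(-a$value))
  .ag_new(tape, y, list(a), backward = function(g) .ag_acc(a, g * y * (1 - y)))
}

ag_relu <- function(tape, a) {
  mask <- a$value > 0
  .ag_new(tape, a$value * mask, list(a),
          backward = function(g) .ag_acc(a, g * mask))
}

ag_leaky_relu <- function(tape, a, slope = 0.2) {
  mask <- a$value > 0
  fac <- ifelse(mask, 1, slope)
  .ag_new(tape, a$value * fac, list(a),
          backward = function(g) .ag_acc(a, g * fac))
}

ag_exp <- function(tape, a) {
  y <- exp(a$value)
  .ag_new(tape, y, list(a), backward = function(g) .ag_acc(a, g * y))
}

# ---- reductions and reshaping --------------------------------------------

ag_rowsums <- function(tape, a) {
  d <- ncol(a$value)
  .ag_new(tape, matrix(rowSums(a$value), ncol = 1L), list(a),
          backward = function(g) .ag_acc(a, matrix(g, nrow(a$value), d)))
}

ag_sum <- function(tape, a) {
  .ag_new(tape, matrix(sum(a$value), 1L, 1L), list(a),
          backward = function(g) {
            .ag_acc(a, matrix(g[1, 1], nrow(a$value), ncol(a$value)))
          })
}

ag_mean <- function(tape, a) {
  nel <- length(a$value)
  .ag_new(tape, matrix(mean(a$value), 1L, 1L), list(a),
          backward = function(g) {
            .ag_acc(a, matrix(g[1, 1] / nel, nrow(a$value), ncol(a$value)))
          })
}

ag_cbind <- function(tape, a, b) {
  na <- ncol(a$value)
  .ag_new(tape, cbind(a$value, b$value), list(a, b), backward = function(g) {
    .ag_acc(a, g[, seq_len(na), drop = FALSE])
    .ag_acc(b, g[, -seq_len(na), drop = FALSE])
  })
}

ag_gather <- function(tape, a, idx) {
  idx <- as.integer(idx)
  n <- nrow(a$value)
  .ag_new(tape, a$value[idx, , drop = FALSE], list(a), backward = function(g) {
    rs <- rowsum(g, idx)
    ga <- matrix(0, n, ncol(a$value))
    ga[as.integer(rownames(rs)), ] <- rs
    .ag_acc(a, ga)
  })
}

ag_scatter_add <- function(tape, a, idx, n_out) {
  idx <- as.integer(idx)
  rs <- rowsum(a$value, idx)
  val <- matrix(0, n_out, ncol(a$value))
  val[as.integer(rownames(rs)), ] <- rs
  .ag_new(tape, val, list(a),
          backward = function(g) .ag_acc(a, g[idx, , drop = FALSE]))
}

# Column-wise max within groups; backward routes gradient to the argmax row
# of each (group, column), ties to the first (lowest-index) row.
ag_group_max <- function(tape, a, idx, n_out) {
  idx <- as.integer(idx)
  d <- ncol(a$value)
  n <- nrow(a$value)
  rows_by_grp <- split(seq_len(n), idx)
  val <- matrix(-Inf, n_out, d)
  amax <- matrix(NA_integer_, n_out, d)
  for (gname in names(rows_by_grp)) {
    gi <- as.integer(gname)
    r <- rows_by_grp[[gname]]
    sub <- a$value[r, , drop = FALSE]
    w <- max.col(t(sub), ties.method = "first")
    val[gi, ] <- sub[cbind(w, seq_len(d))]
    amax[gi, ] <- r[w]
  }
  .ag_new(tape, val, list(a), backward = function(g) {
    ga <- matrix(0, n, d)
    ok <- !is.na(amax)
    cols <- col(amax)[ok]
    lin <- (cols - 1L) * n + amax[ok]
    ga[lin] <- ga[lin] + g[ok]
    .ag_acc(a, ga)
  })
}

# Softmax of a column vector of scores within groups (used for per-node
# attention normalization): alpha_e = exp(s_e - max_grp) / sum_grp.
ag_group_softmax <- function(tape, s, grp) {
  grp <- as.factor(grp)
  sv <- as.vector(s$value)
  m <- stats::ave(sv, grp, FUN = max)
  e <- exp(sv - m)
  denom <- stats::ave(e, grp, FUN = sum)
  alpha <- e / denom
  .ag_new(tape, matrix(alpha, ncol = 1L), list(s), backward = function(g) {
    gv <- as.vector(g)
    dot <- stats::ave(alpha * gv, grp, FUN = sum)
    .ag_acc(s, matrix(alpha * (gv - dot), ncol = 1L))
  })
}

# Row-wise layer normalization with learned gain/bias (1 x d nodes).
ag_layernorm <- function(tape, x, gain, bias, eps = 1e-5) {
  d <- ncol(x$value)
  mu <- rowMeans(x$value)
  xc <- x$value - mu
  v <- rowMeans(xc^2)
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- xc * inv_sd
  gvec <- as.vector(gain$value)
  val <- sweep(xhat, 2L, gvec, `*`)
  val <- sweep(val, 2L, as.vector(bias$value), `+`)
  .ag_new(tape, val, list(x, gain, bias), backward = function(g) {
    dxhat <- sweep(g, 2L, gvec, `*`)
    m1 <- rowMeans(dxhat)
    m2 <- rowMeans(dxhat * xhat)
    dx <- inv_sd * (dxhat - m1 - xhat * m2)
    .ag_acc(x, dx)
    .ag_acc(gain, matrix(colSums(g * xhat), 1L, d))
    .ag_acc(bias, matrix(colSums(g), 1L, d))
  })
}

# Mean smooth-L1 loss against a constant target matrix.
ag_smooth_l1 <- function(tape, pred, target, beta = 1) {
  if (beta <= 0) stop("smooth-L1 beta must be > 0")
  e <- pred$value - target
  ae <- abs(e)
  lv <- ifelse(ae < beta, 0.5 * e^2 / beta, ae - 0.5 * beta)
  nel <- length(e)
  .ag_new(tape, matrix(mean(lv), 1L, 1L), list(pred), backward = function(g) {
    de <- ifelse(ae < beta, e / beta, sign(e))
    .ag_acc(pred, g[1, 1] * de / nel)
  })
}
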