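# The ACTIN network.
#
# One model per cell line. Architecture: (1) drug encoder — atoms one-hot
# over the 14-element vocabulary, embedded to d dimensions, passed through
# two GATv2 + TopK-pooling stages; after each pooling stage a [mean || max]
# readout is taken and the two stage readouts are concatenated and
# projected to the d-dimensional common space (multiscale global
# features); (2) gene projection — a two-layer perceptron mapping the
# 128-d node2vec gene vector into the same space; (3) transpositional
# interfusion — a pre-layer-norm transformer encoder stack over the
# two-token sequence [G_j; D_i] with multi-head attention (heads * d_k =
# d) and an FFN sublayer, both with shortcut additions; (4) head — the two
# fused tokens are flattened and passed through a perceptron with a tanh
# squash, so the interaction score S_ij lives in (-1, 1), the range of the
# step-function targets.

#' ACTIN architecture configuration
#'
#' @param d Common embedding width (default 256). Must be divisible by
#'   both `gat_heads` and `if_heads`.
#' @param gat_heads Attention heads per GATv2 layer (head width `d /
#'   gat_heads`; heads are concatenated so the width stays `d`).
#' @param n_gat_stages Number of GATv2 + TopK-pooling stages.
#' @param pool_ratio TopK pooling keep ratio in (0, 1].
#' @param leaky_slope Negative slope of the LeakyReLU in attention scoring.
#' @param if_heads Interfusion attention heads (default 4; `d_k = d /
#'   if_heads`, 64 at the default width).
#' @param n_blocks Number of interfusion blocks N (default 6).
#' @param ffn_hidden FFN hidden width (default `4 * d`).
#' @param gene_dim Input gene-embedding dimension (default 128).
#' @return An object of class `actin_config`.
#' @export
actin_config <- function(d = 256, gat_heads = 4, n_gat_stages = 2,
                         pool_ratio = 0.8, leaky_slope = 0.2, if_heads = 4,
                         n_blocks = 6, ffn_hidden = 4 * d, gene_dim = 128) {
  if (d %% gat_heads != 0) stop("d must be divisible by gat_heads")
  if (d %% if_heads != 0) stop("d must be divisible by if_heads")
  if (pool_ratio <= 0 || pool_ratio > 1) stop("pool_ratio must lie in (0, 1]")
  if (n_blocks < 1) stop("n_blocks must be >= 1")
  if (n_gat_stages < 1) stop("n_gat_stages must be >= 1")
  structure(list(d = d, gat_heads = gat_heads, gat_head_dim = d %/% gat_heads,
                 n_gat_stages = n_gat_stages, pool_ratio = pool_ratio,
                 leaky_slope = leaky_slope, if_heads = if_heads,
                 d_k = d %/% if_heads, n_blocks = n_blocks,
                 ffn_hidden = ffn_hidden, gene_dim = gene_dim),
            class = "actin_config")
}

.config_hash <- function(cfg) {
  js <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(js), tmp)
  unname(tools::md5sum(tmp))
}

.glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

# Flat named list of all trainable tensors.
init_actin_params <- function(cfg, seed = 1) {
  set.seed(seed)
  d <- cfg$d; hd <- cfg$gat_head_dim; dk <- cfg$d_k; f <- cfg$ffn_hidden
  p <- list()
  p[["atom.W"]] <- .glorot(14L, d)
  p[["atom.b"]] <- matrix(0, 1L, d)
  for (s in seq_len(cfg$n_gat_stages)) {
    for (h in seq_len(cfg$gat_heads)) {
      p[[sprintf("gat%d.h%d.Wl", s, h)]] <- .glorot(d, hd)
      p[[sprintf("gat%d.h%d.Wr", s, h)]] <- .glorot(d, hd)
      p[[sprintf("gat%d.h%d.a", s, h)]] <- .glorot(hd, 1L)
    }
    p[[sprintf("gat%d.b", s)]] <- matrix(0, 1L, d)
    p[[sprintf("topk%d.p", s)]] <- .glorot(d, 1L)
  }
  p[["drugproj.W"]] <- .glorot(2L * d * cfg$n_gat_stages, d)
  p[["drugproj.b"]] <- matrix(0, 1L, d)
  p[["geneproj.W1"]] <- .glorot(cfg$gene_dim, d)
  p[["geneproj.b1"]] <- matrix(0, 1L, d)
  p[["geneproj.W2"]] <- .glorot(d, d)
  p[["geneproj.b2"]] <- matrix(0, 1L, d)
  for (i in seq_len(cfg$n_blocks)) {
    p[[sprintf("blk%d.ln1.g", i)]] <- matrix(1, 1L, d)
    p[[sprintf("blk%d.ln1.b", i)]] <- matrix(0, 1L, d)
    for (h in seq_len(cfg$if_heads)) {
      p[[sprintf("blk%d.h%d.Wq", i, h)]] <- .glorot(d, dk)
      p[[sprintf("blk%d.h%d.Wk", i, h)]] <- .glorot(d, dk)
      p[[sprintf("blk%d.h%d.Wv", i, h)]] <- .glorot(d, dk)
    }
    p[[sprintf("blk%d.Wo", i)]] <- .glorot(cfg$if_heads * dk, d)
    p[[sprintf("blk%d.ln2.g", i)]] <- matrix(1, 1L, d)
    p[[sprintf("blk%d.ln2.b", i)]] <- matrix(0, 1L, d)
    p[[sprintf("blk%d.ffn.W1", i)]] <- .glorot(d, f)
    p[[sprintf("blk%d.ffn.b1", i)]] <- matrix(0, 1L, f)
    p[[sprintf("blk%d.ffn.W2", i)]] <- .glorot(f, d)
    p[[sprintf("blk%d.ffn.b2", i)]] <- matrix(0, 1L, d)
  }
  p[["final.ln.g"]] <- matrix(1, 1L, d)
  p[["final.ln.b"]] <- matrix(0, 1L, d)
  p[["head.W1"]] <- .glorot(2L * d, d)
  p[["head.b1"]] <- matrix(0, 1L, d)
  p[["head.W2"]] <- .glorot(d, 1L)
  p[["head.b2"]] <- matrix(0, 1L, 1L)
  p
}

#' Create an (untrained) per-cell-line ACTIN model
#'
#' @param cell_line Cell-line identifier stamped on the model.
#' @param config An [actin_config()].
#' @param seed Integer seed for parameter initialization.
#' @return An object of class `cell_line_model` with fields `cell_line`,
#'   `config`, `params` (named list of matrices), `seed`, `config_hash`,
#'   `trained`, `history`.
#' @export
new_cell_line_model <- function(cell_line = "CL1", config = actin_config(),
                                seed = 1) {
  structure(list(cell_line = cell_line, config = config,
                 params = init_actin_params(config, seed), seed = seed,
                 config_hash = .config_hash(config), trained = FALSE,
                 history = NULL),
            class = "cell_line_model")
}

#' @export
print.cell_line_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("<cell_line_model> %s: d=%d, %d interfusion blocks, %s, %d parameters\n",
              x$cell_line, x$config$d, x$config$n_blocks,
              if (x$trained) "trained" else "untrained", np))
  invisible(x)
}

# ---- forward passes (tape-based, batched) --------------------------------

.fwd_linear <- function(tape, x, W, b) {
  ag_add(tape, ag_mm(tape, x, W), b)
}

# Stack a list of molecular graphs into one disjoint union.
batch_graphs <- function(graphs) {
  ns <- vapply(graphs, function(g) length(g$elements), integer(1))
  offs <- c(0L, cumsum(ns))
  onehot <- do.call(rbind, lapply(graphs, one_hot_atoms))
  edges <- do.call(rbind, lapply(seq_along(graphs), function(i) {
    e <- graphs[[i]]$edges
    if (nrow(e) == 0L) matrix(integer(), 0, 2) else e + offs[i]
  }))
  gid <- rep(seq_along(graphs), ns)
  elements <- unlist(lapply(graphs, function(g) g$elements))
  list(onehot = onehot, edges = edges, gid = gid, n_graphs = length(graphs),
       elements = elements)
}

# directed edge arrays with self-loops for aggregation
.directed_self <- function(edges, n) {
  if (nrow(edges) > 0L) {
    src <- c(edges[, 1], edges[, 2], seq_len(n))
    dst <- c(edges[, 2], edges[, 1], seq_len(n))
  } else {
    src <- seq_len(n); dst <- seq_len(n)
  }
  list(src = src, dst = dst)
}

# One GATv2 layer over a (batched) graph. H: node (n x d). Returns the
# updated features plus per-head attention values (for interpretability).
.fwd_gat <- function(tape, pn, stage, H, edges, n, cfg) {
  ds <- .directed_self(edges, n)
  grp <- factor(ds$dst, levels = seq_len(n))
  outs <- vector("list", cfg$gat_heads)
  alphas <- vector("list", cfg$gat_heads)
  for (h in seq_len(cfg$gat_heads)) {
    Wl <- pn[[sprintf("gat%d.h%d.Wl", stage, h)]]
    Wr <- pn[[sprintf("gat%d.h%d.Wr", stage, h)]]
    a <- pn[[sprintf("gat%d.h%d.a", stage, h)]]
    Hl <- ag_mm(tape, H, Wl)
    Hr <- ag_mm(tape, H, Wr)
    m <- ag_add(tape, ag_gather(tape, Hl, ds$dst), ag_gather(tape, Hr, ds$src))
    s <- ag_mm(tape, ag_leaky_relu(tape, m, cfg$leaky_slope), a)
    alpha <- ag_group_softmax(tape, s, grp)
    msg <- ag_mul(tape, ag_gather(tape, Hr, ds$src), alpha)
    outs[[h]] <- ag_scatter_add(tape, msg, ds$dst, n)
    alphas[[h]] <- alpha
  }
  Hcat <- outs[[1]]
  if (cfg$gat_heads > 1L) {
    for (h in 2:cfg$gat_heads) Hcat <- ag_cbind(tape, Hcat, outs[[h]])
  }
  Hout <- ag_add(tape, Hcat, pn[[sprintf("gat%d.b", stage)]])
  list(H = Hout, alphas = alphas, src = ds$src, dst = ds$dst)
}

# Canonical atom ranks by Weisfeiler-Lehman color refinement on element
# labels. Atoms in the same final color class are structurally
# indistinguishable (for the tree-plus-one-ring molecules handled here,
# same orbit), so using the color as a pooling tie-break makes node
# selection independent of input atom order.
.wl_ranks <- function(n, edges, elements) {
  colors <- match(elements, atom_vocabulary())
  if (nrow(edges) == 0L) return(colors)
  src <- c(edges[, 1], edges[, 2])
  dst <- c(edges[, 2], edges[, 1])
  for (it in seq_len(max(3L, min(n, 12L)))) {
    nb <- split(colors[src], dst)
    key <- character(n)
    key[] <- as.character(colors)
    has <- as.integer(names(nb))
    key[has] <- paste(colors[has],
                      vapply(nb, function(v) paste(sort(v), collapse = ","),
                             character(1)))
    new_colors <- match(key, sort(unique(key)))
    if (identical(new_colors, colors)) break
    colors <- new_colors
  }
  colors
}

# TopK pooling on a batched graph: keep ceil(ratio * n_g) nodes per graph
# by the learned score (ties broken by canonical WL rank, then node
# index), gate kept features by tanh of the normalized score, induce the
# subgraph.
.fwd_topk <- function(tape, pn, stage, H, edges, gid, cfg, wl = NULL) {
  p <- pn[[sprintf("topk%d.p", stage)]]
  y <- ag_mm(tape, H, p)
  pnorm <- ag_powc(tape, ag_sum(tape, ag_mul(tape, p, p)), 0.5)
  inv <- ag_powc(tape, pnorm, -1)
  score <- ag_mul(tape, y, inv)            # n x 1, scalar broadcast
  gate <- ag_tanh(tape, score)
  sv <- as.vector(score$value)
  n <- length(sv)
  if (is.null(wl)) wl <- rep(0L, n)
  # quantize so float noise from summation order cannot flip the ranking;
  # genuine ties then fall through to the canonical WL rank, then index
  svq <- round(sv, 9)
  keep <- unlist(lapply(split(seq_len(n), gid), function(r) {
    k <- ceiling(cfg$pool_ratio * length(r))
    r[order(-svq[r], wl[r], r)[seq_len(k)]]
  }), use.names = FALSE)
  keep <- sort(keep)
  Hk <- ag_mul(tape, ag_gather(tape, H, keep), ag_gather(tape, gate, keep))
  remap <- rep(NA_integer_, n)
  remap[keep] <- seq_along(keep)
  if (nrow(edges) > 0L) {
    e2 <- cbind(remap[edges[, 1]], remap[edges[, 2]])
    e2 <- e2[stats::complete.cases(e2), , drop = FALSE]
  } else {
    e2 <- matrix(integer(), 0, 2)
  }
  list(H = Hk, edges = e2, gid = gid[keep], keep = keep)
}

# readout = [mean || max] over the nodes of each graph
.fwd_readout <- function(tape, H, gid, n_graphs) {
  cnt <- tabulate(gid, nbins = n_graphs)
  s <- ag_scatter_add(tape, H, gid, n_graphs)
  mean_r <- ag_mul(tape, s, matrix(1 / cnt, ncol = 1L))
  max_r <- ag_group_max(tape, H, gid, n_graphs)
  ag_cbind(tape, mean_r, max_r)
}

# Full drug encoder over a batched graph; returns n_graphs x d node.
# `collect`, if an environment, receives per-stage attention values and
# the element labels of the attended (source) atoms.
.fwd_encode_drug <- function(tape, pn, cfg, bg, collect = NULL) {
  H <- .fwd_linear(tape, ag_const(tape, bg$onehot), pn[["atom.W"]],
                   pn[["atom.b"]])
  edges <- bg$edges
  gid <- bg$gid
  elements <- bg$elements
  readouts <- NULL
  for (s in seq_len(cfg$n_gat_stages)) {
    gat <- .fwd_gat(tape, pn, s, H, edges, length(gid), cfg)
    if (!is.null(collect)) {
      collect$stages[[s]] <- list(
        alphas = lapply(gat$alphas, function(a) as.vector(a$value)),
        src_element = elements[gat$src],
        dst = gat$dst
      )
    }
    wl <- .wl_ranks(length(gid), edges, elements)
    pool <- .fwd_topk(tape, pn, s, gat$H, edges, gid, cfg, wl = wl)
    H <- pool$H
    edges <- pool$edges
    gid <- pool$gid
    elements <- elements[pool$keep]
    r <- .fwd_readout(tape, H, gid, bg$n_graphs)
    readouts <- if (is.null(readouts)) r else ag_cbind(tape, readouts, r)
  }
  .fwd_linear(tape, readouts, pn[["drugproj.W"]], pn[["drugproj.b"]])
}

.fwd_gene_proj <- function(tape, pn, G) {
  h <- ag_relu(tape, .fwd_linear(tape, G, pn[["geneproj.W1"]],
                                 pn[["geneproj.b1"]]))
  .fwd_linear(tape, h, pn[["geneproj.W2"]], pn[["geneproj.b2"]])
}

# One interfusion block over the batched two-token sequences. Xg, Xd are
# B x d nodes (token 1 = gene, token 2 = drug). Pre-LN convention: LN
# before attention and before the FFN; shortcut additions around both.
.fwd_interfusion_block <- function(tape, pn, cfg, i, Xg, Xd,
                                   collect = NULL) {
  ln1g <- pn[[sprintf("blk%d.ln1.g", i)]]
  ln1b <- pn[[sprintf("blk%d.ln1.b", i)]]
  Ng <- ag_layernorm(tape, Xg, ln1g, ln1b)
  Nd <- ag_layernorm(tape, Xd, ln1g, ln1b)
  inv_sqrt_dk <- 1 / sqrt(cfg$d_k)
  Og <- NULL; Od <- NULL
  for (h in seq_len(cfg$if_heads)) {
    Wq <- pn[[sprintf("blk%d.h%d.Wq", i, h)]]
    Wk <- pn[[sprintf("blk%d.h%d.Wk", i, h)]]
    Wv <- pn[[sprintf("blk%d.h%d.Wv", i, h)]]
    Qg <- ag_mm(tape, Ng, Wq); Qd <- ag_mm(tape, Nd, Wq)
    Kg <- ag_mm(tape, Ng, Wk); Kd <- ag_mm(tape, Nd, Wk)
    Vg <- ag_mm(tape, Ng, Wv); Vd <- ag_mm(tape, Nd, Wv)
    sgg <- ag_mul(tape, ag_rowsums(tape, ag_mul(tape, Qg, Kg)), inv_sqrt_dk)
    sgd <- ag_mul(tape, ag_rowsums(tape, ag_mul(tape, Qg, Kd)), inv_sqrt_dk)
    sdg <- ag_mul(tape, ag_rowsums(tape, ag_mul(tape, Qd, Kg)), inv_sqrt_dk)
    sdd <- ag_mul(tape, ag_rowsums(tape, ag_mul(tape, Qd, Kd)), inv_sqrt_dk)
    # two-way row softmax via the logistic of the score difference
    agg <- ag_sigmoid(tape, ag_sub(tape, sgg, sgd))
    agd <- ag_add(tape, ag_neg(tape, agg), 1)
    add <- ag_sigmoid(tape, ag_sub(tape, sdd, sdg))
    adg <- ag_add(tape, ag_neg(tape, add), 1)
    if (!is.null(collect)) {
      collect$blocks[[i]]$heads[[h]] <- cbind(
        a_gg = as.vector(agg$value), a_gd = as.vector(agd$value),
        a_dg = as.vector(adg$value), a_dd = as.vector(add$value)
      )
    }
    Oh_g <- ag_add(tape, ag_mul(tape, Vg, agg), ag_mul(tape, Vd, agd))
    Oh_d <- ag_add(tape, ag_mul(tape, Vg, adg), ag_mul(tape, Vd, add))
    Og <- if (is.null(Og)) Oh_g else ag_cbind(tape, Og, Oh_g)
    Od <- if (is.null(Od)) Oh_d else ag_cbind(tape, Od, Oh_d)
  }
  Wo <- pn[[sprintf("blk%d.Wo", i)]]
  X1g <- ag_add(tape, Xg, ag_mm(tape, Og, Wo))
  X1d <- ag_add(tape, Xd, ag_mm(tape, Od, Wo))
  ln2g <- pn[[sprintf("blk%d.ln2.g", i)]]
  ln2b <- pn[[sprintf("blk%d.ln2.b", i)]]
  ffn <- function(Xn) {
    h1 <- ag_relu(tape, .fwd_linear(tape, Xn, pn[[sprintf("blk%d.ffn.W1", i)]],
                                    pn[[sprintf("blk%d.ffn.b1", i)]]))
    .fwd_linear(tape, h1, pn[[sprintf("blk%d.ffn.W2", i)]],
                pn[[sprintf("blk%d.ffn.b2", i)]])
  }
  list(
    Xg = ag_add(tape, X1g, ffn(ag_layernorm(tape, X1g, ln2g, ln2b))),
    Xd = ag_add(tape, X1d, ffn(ag_layernorm(tape, X1d, ln2g, ln2b)))
  )
}

.fwd_head <- function(tape, pn, cfg, Xg, Xd) {
  # final layer norm of the pre-LN convention: keeps the flattened tokens
  # in a range where the tanh squash does not saturate
  Xg <- ag_layernorm(tape, Xg, pn[["final.ln.g"]], pn[["final.ln.b"]])
  Xd <- ag_layernorm(tape, Xd, pn[["final.ln.g"]], pn[["final.ln.b"]])
  Z <- ag_cbind(tape, Xg, Xd)
  h <- ag_relu(tape, .fwd_linear(tape, Z, pn[["head.W1"]], pn[["head.b1"]]))
  ag_tanh(tape, .fwd_linear(tape, h, pn[["head.W2"]], pn[["head.b2"]]))
}

# Full forward: batched graphs + gene matrix (B x gene_dim) + for each of
# the B pairs the index of its drug graph. Returns the score node (B x 1).
.fwd_actin <- function(tape, pn, cfg, bg, gene_mat, pair_drug, collect = NULL) {
  D_all <- .fwd_encode_drug(tape, pn, cfg, bg, collect)
  Xd <- ag_gather(tape, D_all, pair_drug)
  Xg <- .fwd_gene_proj(tape, pn, ag_const(tape, gene_mat))
  for (i in seq_len(cfg$n_blocks)) {
    blk <- .fwd_interfusion_block(tape, pn, cfg, i, Xg, Xd, collect)
    Xg <- blk$Xg
    Xd <- blk$Xd
  }
  .fwd_head(tape, pn, cfg, Xg, Xd)
}

.params_as_nodes <- function(tape, params, trainable = TRUE) {
  f <- if (trainable) ag_param else ag_const
  lapply(params, function(p) f(tape, p))
}

# ---- public layer-level operations ---------------------------------------

#' Embed one-hot atoms into the common space
#'
#' Shared per-element linear map: two atoms of the same element always get
#' identical embedding rows.
#'
#' @param one_hot `n x 14` one-hot matrix ([one_hot_atoms()]).
#' @param model A `cell_line_model` (or a list with `atom.W`, `atom.b`).
#' @return `n x d` numeric matrix.
#' @export
embed_atoms <- function(one_hot, model) {
  p <- if (inherits(model, "cell_line_model")) model$params else model
  if (ncol(one_hot) != nrow(p[["atom.W"]])) {
    stop("one-hot matrix must have ", nrow(p[["atom.W"]]), " columns")
  }
  one_hot %*% p[["atom.W"]] +
    matrix(p[["atom.b"]], nrow(one_hot), ncol(p[["atom.W"]]), byrow = TRUE)
}

#' Run one GATv2 layer on a molecular graph
#'
#' Attention scoring per head h: `e_h(i,j) = a_h' LeakyReLU(Wl_h x_i +
#' Wr_h x_j)` for j in N(i) plus a self-loop, normalized with a softmax
#' over each node's neighbourhood; updated features are the
#' attention-weighted sums of `Wr_h x_j`, concatenated over heads.
#'
#' @param features `n x d` feature matrix.
#' @param edges Two-column undirected edge matrix.
#' @param params List with `heads` (a list of `list(Wl, Wr, a)`) and a bias
#'   row `b`; see [gatv2_params()].
#' @param leaky_slope Negative slope of the scoring LeakyReLU.
#' @return List with `features` (`n x (heads * head_dim)`) and `attention`,
#'   a list (one per head) of data.frames `src`, `dst`, `alpha` including
#'   self-loops; per `dst` the alphas sum to 1.
#' @export
gatv2_layer <- function(features, edges, params, leaky_slope = 0.2) {
  n <- nrow(features)
  if (is.null(n) || n == 0L) stop("empty graph: features must have rows")
  tape <- ag_tape()
  H <- ag_const(tape, features)
  ds <- .directed_self(matrix(as.integer(edges), ncol = 2), n)
  grp <- factor(ds$dst, levels = seq_len(n))
  outs <- list(); att <- list()
  for (h in seq_along(params$heads)) {
    ph <- params$heads[[h]]
    Hl <- ag_mm(tape, H, ag_const(tape, ph$Wl))
    Hr <- ag_mm(tape, H, ag_const(tape, ph$Wr))
    m <- ag_add(tape, ag_gather(tape, Hl, ds$dst), ag_gather(tape, Hr, ds$src))
    s <- ag_mm(tape, ag_leaky_relu(tape, m, leaky_slope), ag_const(tape, ph$a))
    alpha <- ag_group_softmax(tape, s, grp)
    msg <- ag_mul(tape, ag_gather(tape, Hr, ds$src), alpha)
    outs[[h]] <- ag_value(ag_scatter_add(tape, msg, ds$dst, n))
    att[[h]] <- data.frame(src = ds$src, dst = ds$dst,
                           alpha = as.vector(alpha$value))
  }
  feat <- do.call(cbind, outs)
  if (!is.null(params$b)) {
    feat <- feat + matrix(params$b, n, ncol(feat), byrow = TRUE)
  }
  list(features = feat, attention = att)
}

#' Random GATv2 layer parameters
#'
#' @param in_dim Input feature width.
#' @param heads Number of heads.
#' @param head_dim Output width per head.
#' @param seed RNG seed.
#' @return Parameter list usable with [gatv2_layer()].
#' @export
gatv2_params <- function(in_dim, heads = 4, head_dim = 16, seed = 1) {
  set.seed(seed)
  list(heads = lapply(seq_len(heads), function(h) {
    list(Wl = .glorot(in_dim, head_dim), Wr = .glorot(in_dim, head_dim),
         a = .glorot(head_dim, 1L))
  }), b = matrix(0, 1L, heads * head_dim))
}

#' TopK pooling of a molecular graph
#'
#' Scores nodes by a learned projection (`score = X p / ||p||`), keeps the
#' `ceiling(ratio * n)` highest-scoring nodes (ties broken by lower node
#' index), gates kept features by `tanh(score)` and induces the subgraph.
#'
#' @param features `n x d` feature matrix.
#' @param edges Two-column undirected edge matrix.
#' @param params List with score vector `p` (`d x 1`).
#' @param ratio Keep ratio in (0, 1].
#' @return List `features`, `edges`, `kept` (indices into the input,
#'   ascending).
#' @export
topk_pool <- function(features, edges, params, ratio = 0.8) {
  if (ratio <= 0 || ratio > 1) stop("ratio must lie in (0, 1]")
  n <- nrow(features)
  p <- as.matrix(params$p)
  score <- as.vector(features %*% p) / sqrt(sum(p^2))
  k <- ceiling(ratio * n)
  keep <- sort(order(-score, seq_len(n))[seq_len(k)])
  feat <- features[keep, , drop = FALSE] * tanh(score[keep])
  remap <- rep(NA_integer_, n)
  remap[keep] <- seq_along(keep)
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges) > 0L) {
    e2 <- cbind(remap[edges[, 1]], remap[edges[, 2]])
    e2 <- e2[stats::complete.cases(e2), , drop = FALSE]
  } else {
    e2 <- matrix(integer(), 0, 2)
  }
  list(features = feat, edges = e2, kept = keep)
}

#' Encode a drug molecule into the common space
#'
#' @param graph A [molecular_graph()] (or SMILES string).
#' @param model A `cell_line_model`.
#' @return Numeric vector of length `model$config$d` (D_i).
#' @export
encode_drug <- function(graph, model) {
  if (is.character(graph)) graph <- parse_smiles(graph)
  stopifnot(inherits(model, "cell_line_model"))
  tape <- ag_tape()
  pn <- .params_as_nodes(tape, model$params, trainable = FALSE)
  bg <- batch_graphs(list(graph))
  as.vector(ag_value(.fwd_encode_drug(tape, pn, model$config, bg)))
}

#' Project a gene embedding into the common space
#'
#' @param embedding Numeric vector of length `model$config$gene_dim`.
#' @param model A `cell_line_model`.
#' @return Numeric vector of length `model$config$d` (G_j).
#' @export
project_gene <- function(embedding, model) {
  stopifnot(inherits(model, "cell_line_model"))
  if (length(embedding) != model$config$gene_dim || any(!is.finite(embedding))) {
    stop("gene embedding must be a finite vector of length ",
         model$config$gene_dim)
  }
  tape <- ag_tape()
  pn <- .params_as_nodes(tape, model$params, trainable = FALSE)
  G <- ag_const(tape, matrix(embedding, nrow = 1L))
  as.vector(ag_value(.fwd_gene_proj(tape, pn, G)))
}

#' Apply one interfusion block to a two-token sequence
#'
#' @param X `2 x d` matrix: row 1 the gene token, row 2 the drug token.
#' @param model A `cell_line_model`.
#' @param block Block index (1-based).
#' @return List with `X` (the `2 x d` output) and `attention`, one `2 x 2`
#'   row-stochastic matrix per head.
#' @export
interfusion_block <- function(X, model, block = 1) {
  stopifnot(inherits(model, "cell_line_model"))
  cfg <- model$config
  if (!all(dim(X) == c(2L, cfg$d))) stop("X must be 2 x ", cfg$d)
  tape <- ag_tape()
  pn <- .params_as_nodes(tape, model$params, trainable = FALSE)
  collect <- new.env()
  collect$blocks <- vector("list", block)
  out <- .fwd_interfusion_block(tape, pn, cfg, block,
                                ag_const(tape, X[1, , drop = FALSE]),
                                ag_const(tape, X[2, , drop = FALSE]),
                                collect = collect)
  att <- lapply(collect$blocks[[block]]$heads, function(a) {
    matrix(c(a[1, "a_gg"], a[1, "a_gd"], a[1, "a_dg"], a[1, "a_dd"]),
           2L, 2L, byrow = TRUE,
           dimnames = list(c("gene", "drug"), c("gene", "drug")))
  })
  list(X = rbind(ag_value(out$Xg), ag_value(out$Xd)), attention = att)
}

#' Predict the interaction score for one (gene, drug) vector pair
#'
#' Stacks G_j and D_i, runs the N interfusion blocks and the bounded head.
#'
#' @param G Gene vector in the common space (length d).
#' @param D Drug vector in the common space (length d).
#' @param model A `cell_line_model`.
#' @return Scalar score in (-1, 1).
#' @export
predict_score <- function(G, D, model) {
  stopifnot(inherits(model, "cell_line_model"))
  cfg <- model$config
  if (length(G) != cfg$d || length(D) != cfg$d) stop("G and D must have length ", cfg$d)
  if (any(!is.finite(G)) || any(!is.finite(D))) stop("G and D must be finite")
  tape <- ag_tape()
  pn <- .params_as_nodes(tape, model$params, trainable = FALSE)
  Xg <- ag_const(tape, matrix(G, nrow = 1L))
  Xd <- ag_const(tape, matrix(D, nrow = 1L))
  for (i in seq_len(cfg$n_blocks)) {
    blk <- .fwd_interfusion_block(tape, pn, cfg, i, Xg, Xd)
    Xg <- blk$Xg; Xd <- blk$Xd
  }
  ag_value(.fwd_head(tape, pn, cfg, Xg, Xd))[1, 1]
}

# ---- checkpoints ----------------------------------------------------------

#' Save a cell-line model checkpoint
#'
#' Single-file JSON archive: a config block plus named parameter arrays
#' (full double precision). Loading validates the config hash.
#'
#' @param model A `cell_line_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_cell_line_model <- function(model, path) {
  stopifnot(inherits(model, "cell_line_model"))
  obj <- list(
    format = "actin-checkpoint-1",
    cell_line = model$cell_line,
    config = unclass(model$config),
    config_hash = model$config_hash,
    seed = model$seed,
    trained = model$trained,
    history = model$history,
    params = lapply(model$params, function(m) {
      list(dim = dim(m), data = as.vector(m))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a cell-line model checkpoint
#'
#' @param path Path written by [save_cell_line_model()].
#' @return A `cell_line_model`.
#' @export
load_cell_line_model <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format) || obj$format != "actin-checkpoint-1") {
    stop("'", path, "' is not an ACTIN checkpoint")
  }
  cfg <- structure(as.list(obj$config), class = "actin_config")
  if (.config_hash(cfg) != obj$config_hash) {
    stop("checkpoint config hash mismatch in '", path, "'")
  }
  params <- lapply(obj$params, function(p) matrix(p$data, p$dim[1], p$dim[2]))
  history <- if (!is.null(obj$history) && length(obj$history)) {
    as.data.frame(obj$history)
  } else NULL
  structure(list(cell_line = obj$cell_line, config = cfg, params = params,
                 seed = obj$seed, config_hash = obj$config_hash,
                 trained = isTRUE(obj$trained), history = history),
            class = "cell_line_model")
}
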