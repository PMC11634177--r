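# Gene embeddings from a PPI network.
#
# Landmark genes are embedded into a low-dimensional space with a
# node2vec-style procedure: biased second-order random walks over the PPI
# graph feed a skip-gram model trained with negative sampling. Genes that
# share network neighbourhoods end up with similar vectors, giving the
# downstream network a geometry over genes instead of opaque one-hot ids.
# Training uses seeded mini-batch SGD with within-batch gradient
# aggregation, so results are bit-reproducible for a given seed.

#' Learn gene embeddings from a PPI edge list (node2vec)
#'
#' @param edges Data.frame or matrix with two columns of gene ids (an
#'   optional third score column is ignored).
#' @param dim Embedding dimension (default 128).
#' @param walk_length Nodes per random walk.
#' @param walks_per_node Walks started from each node.
#' @param window Skip-gram window (context offsets 1..window on each side).
#' @param p Return parameter of the biased walk (1 = unbiased).
#' @param q In-out parameter of the biased walk (1 = unbiased).
#' @param n_negative Negative samples per positive pair.
#' @param epochs Passes over the generated pairs.
#' @param lr Initial SGD learning rate (decays linearly to lr/100).
#' @param batch_size Pairs per SGD mini-batch.
#' @param seed Integer RNG seed.
#' @param giant_component If TRUE, embed only the largest connected
#'   component of a disconnected graph instead of erroring.
#' @return A `gene_embedding` object: numeric matrix (genes x dim) with
#'   gene ids as rownames and attributes `source = "trained"` and `dim`.
#' @export
node2vec_embed <- function(edges, dim = 128, walk_length = 80,
                           walks_per_node = 10, window = 5, p = 1, q = 1,
                           n_negative = 5, epochs = 5, lr = 0.025,
                           batch_size = 1000, seed = 1,
                           giant_component = FALSE) {
  if (dim < 2) stop("dim must be at least 2")
  el <- as.data.frame(edges)[, 1:2]
  ids <- sort(unique(c(as.character(el[[1]]), as.character(el[[2]]))))
  g <- igraph::graph_from_edgelist(
    cbind(match(as.character(el[[1]]), ids), match(as.character(el[[2]]), ids)),
    directed = FALSE
  )
  g <- igraph::simplify(g)
  comps <- igraph::components(g)
  if (comps$no > 1L) {
    if (!giant_component) {
      sizes <- sort(comps$csize, decreasing = TRUE)
      stop("PPI graph is disconnected (", comps$no, " components of sizes ",
           paste(sizes, collapse = ", "),
           "); set giant_component = TRUE to embed the largest component")
    }
    keep <- which(comps$membership == which.max(comps$csize))
    g <- igraph::induced_subgraph(g, keep)
    ids <- ids[keep]
  }
  n <- igraph::vcount(g)
  set.seed(seed)
  adj <- igraph::as_adj_list(g)
  adj <- lapply(adj, function(v) sort(as.integer(v)))  # edge-order invariance
  deg <- lengths(adj)
  adj_flat <- unlist(adj)
  adj_start <- c(0L, cumsum(deg))  # neighbours of v: adj_flat[adj_start[v] + 1..deg[v]]

  walks <- .n2v_walks(adj, adj_flat, adj_start, deg, n, walk_length,
                      walks_per_node, p, q)
  pairs <- .skipgram_pairs(walks, window)
  emb <- .sgns_train(pairs, n, dim, n_negative, epochs, lr, batch_size)
  rownames(emb) <- ids
  structure(emb, source = "trained", embedding_dim = dim, class = "gene_embedding")
}

# Random walks. For p = q = 1 every step is a uniform neighbour draw and is
# vectorized across all walks; otherwise the second-order bias is applied
# walk by walk.
.n2v_walks <- function(adj, adj_flat, adj_start, deg, n, walk_length,
                       walks_per_node, p, q) {
  starts <- rep(seq_len(n), each = walks_per_node)
  n_walks <- length(starts)
  W <- matrix(0L, n_walks, walk_length)
  W[, 1] <- starts
  if (p == 1 && q == 1) {
    cur <- starts
    for (t in seq_len(walk_length - 1L)) {
      pick <- floor(stats::runif(n_walks) * deg[cur]) + 1L
      cur <- adj_flat[adj_start[cur] + pick]
      W[, t + 1L] <- cur
    }
  } else {
    for (wk in seq_len(n_walks)) {
      prev <- NA_integer_
      cur <- starts[wk]
      for (t in seq_len(walk_length - 1L)) {
        nb <- adj[[cur]]
        if (is.na(prev)) {
          nxt <- nb[sample.int(length(nb), 1L)]
        } else {
          wgt <- ifelse(nb == prev, 1 / p,
                        ifelse(nb %in% adj[[prev]], 1, 1 / q))
          nxt <- nb[sample.int(length(nb), 1L, prob = wgt)]
        }
        W[wk, t + 1L] <- nxt
        prev <- cur
        cur <- nxt
      }
    }
  }
  W
}

# All (center, context) pairs within the window, both directions.
.skipgram_pairs <- function(W, window) {
  L <- ncol(W)
  centers <- integer(0); contexts <- integer(0)
  for (off in seq_len(min(window, L - 1L))) {
    a <- as.vector(W[, seq_len(L - off)])
    b <- as.vector(W[, seq_len(L - off) + off])
    centers <- c(centers, a, b)
    contexts <- c(contexts, b, a)
  }
  cbind(center = centers, context = contexts)
}

# Skip-gram with negative sampling; mini-batch SGD, gradients aggregated
# within a batch by rowsum so updates are order-deterministic.
.sgns_train <- function(pairs, n, dim, n_negative, epochs, lr, batch_size) {
  U <- matrix((stats::runif(n * dim) - 0.5) / dim, n, dim)   # input vectors
  V <- matrix(0, n, dim)                                     # output vectors
  cnt <- tabulate(pairs[, 1], nbins = n)
  neg_prob <- (cnt + 1)^0.75
  neg_prob <- neg_prob / sum(neg_prob)
  neg_cdf <- cumsum(neg_prob)
  np <- nrow(pairs)
  n_batches_total <- epochs * ceiling(np / batch_size)
  step <- 0L
  sigm <- function(x) 1 / (1 + exp(-x))
  for (ep in seq_len(epochs)) {
    ord <- sample.int(np)
    for (b0 in seq(1L, np, by = batch_size)) {
      step <- step + 1L
      cur_lr <- lr * max(0.01, 1 - step / n_batches_total)
      idx <- ord[b0:min(b0 + batch_size - 1L, np)]
      ci <- pairs[idx, 1]; oj <- pairs[idx, 2]
      m <- length(idx)
      gU <- matrix(0, m, dim)
      # positive pairs (label 1)
      sc <- sigm(rowSums(U[ci, , drop = FALSE] * V[oj, , drop = FALSE])) - 1
      gU <- gU + sc * V[oj, , drop = FALSE]
      gV_rows <- sc * U[ci, , drop = FALSE]
      gV_idx <- oj
      # negative pairs (label 0)
      for (k in seq_len(n_negative)) {
        nj <- findInterval(stats::runif(m), neg_cdf) + 1L
        scn <- sigm(rowSums(U[ci, , drop = FALSE] * V[nj, , drop = FALSE]))
        gU <- gU + scn * V[nj, , drop = FALSE]
        gV_rows <- rbind(gV_rows, scn * U[ci, , drop = FALSE])
        gV_idx <- c(gV_idx, nj)
      }
      # aggregated per-node gradients, norm-clipped so that nodes that
      # recur many times in one batch (small graphs) cannot blow up
      clip <- function(g, max_norm = 1) {
        nrm <- sqrt(rowSums(g^2))
        fac <- pmin(1, max_norm / pmax(nrm, 1e-12))
        g * fac
      }
      agg_u <- clip(rowsum(gU, ci))
      iu <- as.integer(rownames(agg_u))
      U[iu, ] <- U[iu, ] - cur_lr * agg_u
      agg_v <- clip(rowsum(gV_rows, gV_idx))
      iv <- as.integer(rownames(agg_v))
      V[iv, ] <- V[iv, ] - cur_lr * agg_v
    }
  }
  U
}

#' Wrap a plain matrix as a gene-embedding table
#'
#' @param mat Numeric matrix with gene ids as rownames.
#' @param source `"trained"` or `"loaded"`.
#' @return A `gene_embedding` object.
#' @export
as_gene_embedding <- function(mat, source = "loaded") {
  mat <- as.matrix(mat)
  if (is.null(rownames(mat))) stop("embedding matrix needs gene ids as rownames")
  if (anyDuplicated(rownames(mat))) {
    stop("duplicate gene_id: ",
         paste(unique(rownames(mat)[duplicated(rownames(mat))]), collapse = ", "))
  }
  if (any(!is.finite(mat))) stop("embedding values must be finite")
  structure(mat, source = source, embedding_dim = ncol(mat), class = "gene_embedding")
}

#' Read a gene-embedding table from TSV
#'
#' Expected header: `gene_id`, `e1` ... `e<dim>`. Ragged rows, duplicate
#' gene ids and empty files are rejected.
#'
#' @param path File path.
#' @return A `gene_embedding` object with `source = "loaded"`.
#' @export
read_embedding_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L) stop("embedding table '", path,
                               "' is empty (header plus at least one row required)")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  widths <- lengths(parts)
  if (any(widths != widths[1])) {
    bad <- which(widths != widths[1])[1]
    stop("ragged embedding table at line ", bad, ": expected ", widths[1],
         " fields, found ", widths[bad])
  }
  header <- parts[[1]]
  if (header[1] != "gene_id") stop("embedding table must start with a gene_id column")
  ids <- vapply(parts[-1], `[`, character(1), 1)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    ln <- which(ids %in% dup) + 1L
    stop("duplicate gene_id (", paste(dup, collapse = ", "), ") at line(s) ",
         paste(ln, collapse = ", "))
  }
  vals <- t(vapply(parts[-1], function(r) as.numeric(r[-1]),
                   numeric(length(header) - 1L)))
  if (any(!is.finite(vals))) stop("non-finite embedding value in '", path, "'")
  rownames(vals) <- ids
  colnames(vals) <- header[-1]
  as_gene_embedding(vals, source = "loaded")
}

#' Write a gene-embedding table to TSV
#'
#' Values are written with enough digits that a write/read round trip is
#' lossless to well below 1e-8.
#'
#' @param table A `gene_embedding` object (or matrix with rownames).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_embedding_table <- function(table, path) {
  mat <- unclass(table)
  header <- paste(c("gene_id", paste0("e", seq_len(ncol(mat)))), collapse = "\t")
  rows <- vapply(seq_len(nrow(mat)), function(i) {
    paste(c(rownames(mat)[i], sprintf("%.12g", mat[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a PPI edge list from TSV
#'
#' Two gene-id columns; an optional third (score) column is ignored. A
#' header line is detected and skipped if its second field is non-numeric
#' and equals common column names.
#'
#' @param path File path.
#' @return Data.frame with columns `gene_a`, `gene_b`.
#' @export
read_ppi_edges <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("PPI edge list needs two columns")
  if (tolower(df[1, 1]) %in% c("gene_a", "gene1", "protein1", "gene_id")) {
    df <- df[-1, , drop = FALSE]
  }
  data.frame(gene_a = as.character(df[[1]]), gene_b = as.character(df[[2]]))
}
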