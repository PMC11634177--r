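# Interpretability analyses.
#
# Two procedures: (1) element-embedding disparity — across a family of
# per-cell-line models, how differently is each chemical element embedded?
# The 14 x d element matrices of all models are stacked, PCA-reduced, and
# the per-component range and sd across models are accumulated per
# element; elements whose embeddings vary most across cell lines are the
# ones whose pharmacophores the models treat in a line-specific way.
# (2) attention element importance — within one model, how much GATv2
# attention mass flows from atoms of each element? Fractions are reported
# per attention head with a mean row, mirroring per-head heatmaps.

#' Extract the element embedding matrix of a model
#'
#' Row e is the common-space embedding of the e-th vocabulary element,
#' i.e. [embed_atoms()] applied to the 14 unit one-hot vectors.
#'
#' @param model A `cell_line_model`.
#' @return `14 x d` matrix with vocabulary rownames.
#' @export
extract_element_embeddings <- function(model) {
  stopifnot(inherits(model, "cell_line_model"))
  m <- embed_atoms(diag(14), model)
  rownames(m) <- atom_vocabulary()
  m
}

#' PCA reduction of a stacked embedding matrix
#'
#' Principal components of the row-centered matrix, by descending
#' variance. The number of components is clipped to
#' `min(n_components, rows - 1, cols)`.
#'
#' @param x Numeric matrix (>= 2 rows).
#' @param n_components Requested number of components (default 128).
#' @return List with `scores` (rows x k), `rotation`, `center`,
#'   `explained` (variance fractions, length k).
#' @export
reduce_pca <- function(x, n_components = 128) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("PCA needs at least 2 rows")
  k <- min(n_components, nrow(x) - 1L, ncol(x))
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       rotation = pc$rotation[, seq_len(k), drop = FALSE],
       center = pc$center,
       explained = (ev / sum(ev))[seq_len(k)])
}

#' Element-embedding disparity across a family of cell-line models
#'
#' Stacks every model's element matrix, PCA-reduces the stack, then for
#' each element computes the range (max - min) and sd of its reduced
#' coordinates across models, per component; cumulative disparity is the
#' plain sum over components. Elements are ranked by descending
#' cumulative disparity.
#'
#' @param models List of >= 2 `cell_line_model` objects (same config).
#' @param n_components PCA components (default 128, clipped).
#' @param top_k Size of the reported top slice (default 5).
#' @param rank_by `"range"` (default) or `"sd"`.
#' @return An `element_disparity` report: list with `n_components`,
#'   `explained`, `range` / `sd` (14 x k matrices), `cumulative`
#'   (data.frame element / cum_range / cum_sd), `ranking` (all 14
#'   elements, descending), `top` (first `top_k`).
#' @export
disparity_report <- function(models, n_components = 128, top_k = 5,
                             rank_by = c("range", "sd")) {
  rank_by <- match.arg(rank_by)
  if (length(models) < 2L) stop("disparity needs at least 2 models")
  mats <- lapply(models, extract_element_embeddings)
  stacked <- do.call(rbind, mats)
  red <- reduce_pca(stacked, n_components)
  k <- ncol(red$scores)
  n_mod <- length(models)
  vocab <- atom_vocabulary()
  rng <- matrix(0, 14L, k, dimnames = list(vocab, colnames(red$scores)))
  sdv <- rng
  for (e in seq_len(14L)) {
    rows <- red$scores[e + 14L * (seq_len(n_mod) - 1L), , drop = FALSE]
    rng[e, ] <- apply(rows, 2L, function(v) max(v) - min(v))
    sdv[e, ] <- apply(rows, 2L, stats::sd)
  }
  cum <- data.frame(element = vocab, cum_range = rowSums(rng),
                    cum_sd = rowSums(sdv))
  key <- if (rank_by == "range") cum$cum_range else cum$cum_sd
  ranking <- vocab[order(-key, vocab)]
  structure(list(n_components = k, explained = red$explained, range = rng,
                 sd = sdv, cumulative = cum, ranking = ranking,
                 top = ranking[seq_len(min(top_k, 14L))], rank_by = rank_by),
            class = "element_disparity")
}

#' @export
print.element_disparity <- function(x, ...) {
  cat(sprintf("<element_disparity> %d components, ranked by cumulative %s\n",
              x$n_components, x$rank_by))
  cat("top elements:", paste(x$top, collapse = ", "), "\n")
  invisible(x)
}

#' Attention-based element importance of one model
#'
#' Runs the drug encoder over a molecule set, accumulates the incoming
#' GATv2 attention mass at the chosen stage grouped by the element of the
#' attended (source) atom — self-loops included — and normalizes per head
#' so each head's fractions sum to 1. A mean row over heads is appended.
#'
#' @param model A `cell_line_model`.
#' @param molecules List of [molecular_graph()] objects (or character
#'   SMILES vector); non-empty.
#' @param stage Which GATv2 stage's attention to read (default 1, the
#'   layer closest to raw chemistry).
#' @return An `element_importance` matrix: `(heads + 1) x 14`, rows
#'   `head1..headH, mean`, columns in vocabulary order; each head row
#'   sums to 1.
#' @export
attention_element_importance <- function(model, molecules, stage = 1) {
  stopifnot(inherits(model, "cell_line_model"))
  if (is.character(molecules)) molecules <- lapply(molecules, parse_smiles)
  if (length(molecules) == 0L) stop("molecule set must be non-empty")
  cfg <- model$config
  if (stage < 1 || stage > cfg$n_gat_stages) {
    stop("stage must lie in 1..", cfg$n_gat_stages)
  }
  vocab <- atom_vocabulary()
  mass <- matrix(0, cfg$gat_heads, 14L, dimnames = list(NULL, vocab))
  chunk <- 200L
  for (b0 in seq(1L, length(molecules), by = chunk)) {
    sub <- molecules[b0:min(b0 + chunk - 1L, length(molecules))]
    bg <- batch_graphs(sub)
    tape <- ag_tape()
    pn <- .params_as_nodes(tape, model$params, trainable = FALSE)
    collect <- new.env()
    collect$stages <- list()
    .fwd_encode_drug(tape, pn, cfg, bg, collect)
    st <- collect$stages[[stage]]
    f <- factor(st$src_element, levels = vocab)
    for (h in seq_len(cfg$gat_heads)) {
      acc <- tapply(st$alphas[[h]], f, sum, default = 0)
      mass[h, ] <- mass[h, ] + acc
    }
  }
  frac <- mass / rowSums(mass)
  out <- rbind(frac, mean = colMeans(frac))
  rownames(out) <- c(paste0("head", seq_len(cfg$gat_heads)), "mean")
  structure(out, class = c("element_importance", "matrix"))
}
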