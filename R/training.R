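# Per-cell-line training.
#
# Training samples are (drug, gene) pairs: one pair per perturbation
# record, with the step-function-mapped logFC as regression target.
# Splitting happens at the perturbation-instance level (drug x cell line),
# so all genes measured under one treatment share a fold and no
# treatment leaks across folds. One model is trained per cell line with
# smooth-L1 loss, Adam, seeded shuffling, and (when a validation fold
# exists) early stopping on validation loss.

#' Training configuration
#'
#' @param batch_size Pairs per mini-batch (default 1000).
#' @param lr Adam learning rate.
#' @param epochs Maximum epochs.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement); only used when a validation fold exists.
#' @param split Named fractions summing to 1: either `c(train=, test=)` or
#'   `c(train=, val=, test=)`.
#' @param beta Smooth-L1 transition point.
#' @param seed Seed governing parameter init, splits and shuffles.
#' @return An object of class `train_config`.
#' @export
train_config <- function(batch_size = 1000, lr = 1e-4, epochs = 50,
                         patience = 10, split = c(train = 0.8, test = 0.2),
                         beta = 1, seed = 1) {
  if (batch_size < 1) stop("batch_size must be >= 1")
  if (lr <= 0) stop("lr must be > 0")
  if (beta <= 0) stop("smooth-L1 beta must be > 0")
  if (abs(sum(split) - 1) > 1e-8) stop("split fractions must sum to 1")
  if (!(length(split) %in% c(2L, 3L))) stop("split must have 2 or 3 folds")
  structure(list(batch_size = as.integer(batch_size), lr = lr,
                 epochs = as.integer(epochs), patience = as.integer(patience),
                 split = split, beta = beta, seed = as.integer(seed)),
            class = "train_config")
}

#' Mean smooth-L1 loss
#'
#' `0.5 e^2 / beta` for `|e| < beta`, else `|e| - beta/2`, with
#' `e = pred - target`; averaged over the batch.
#'
#' @param pred,target Numeric vectors of equal length (finite).
#' @param beta Transition point (> 0).
#' @return Non-negative scalar.
#' @export
smooth_l1 <- function(pred, target, beta = 1) {
  if (beta <= 0) stop("smooth-L1 beta must be > 0")
  if (any(!is.finite(pred)) || any(!is.finite(target))) {
    stop("smooth_l1 inputs must be finite")
  }
  e <- pred - target
  ae <- abs(e)
  mean(ifelse(ae < beta, 0.5 * e^2 / beta, ae - 0.5 * beta))
}

#' Assign perturbation instances to folds
#'
#' Instances (drug x cell line treatments) are shuffled with the seed and
#' assigned contiguously: every fold except the last receives
#' `floor(fraction * n)` instances, the last takes the remainder.
#'
#' @param instances Character vector of instance ids (e.g. drug ids).
#' @param split Named fractions as in [train_config()] (`train`/`test` or
#'   `train`/`val`/`test`).
#' @param seed Integer seed.
#' @return Named character vector: fold label per instance id.
#' @export
split_instances <- function(instances, split = c(train = 0.8, test = 0.2),
                            seed = 1) {
  instances <- as.character(instances)
  n <- length(instances)
  if (n == 0L) stop("no instances to split")
  if (abs(sum(split) - 1) > 1e-8) stop("split fractions must sum to 1")
  fold_names <- names(split)
  if (is.null(fold_names)) {
    fold_names <- if (length(split) == 2L) c("train", "test")
                  else c("train", "val", "test")
  }
  sizes <- floor(split * n)
  sizes[length(sizes)] <- n - sum(sizes[-length(sizes)])
  if (any(split > 0 & sizes == 0)) {
    stop("too few instances (", n, ") for the requested non-empty folds")
  }
  set.seed(seed)
  ord <- sample(instances)
  fold <- rep(fold_names, sizes)
  stats::setNames(fold[match(instances, ord)], instances)
}

#' Build (drug, gene) pair samples from perturbation records
#'
#' @param records Perturbation data.frame with columns `drug_id`, `smiles`,
#'   `cell_line`, `gene_id`, `logFC`.
#' @param embeddings A `gene_embedding` table covering every `gene_id`.
#' @param sf An [sf_params()]; targets are `step_function(logFC, sf)`.
#' @return List with `samples` (data.frame `drug_id`, `gene_id`,
#'   `cell_line`, `logFC`, `target`, `label`) and `graphs` (named list of
#'   parsed molecular graphs, one per drug).
#' @export
build_pairs <- function(records, embeddings, sf = sf_params()) {
  req <- c("drug_id", "smiles", "cell_line", "gene_id", "logFC")
  miss <- setdiff(req, names(records))
  if (length(miss) > 0L) stop("records missing column(s): ",
                              paste(miss, collapse = ", "))
  missing_genes <- setdiff(unique(records$gene_id), rownames(embeddings))
  if (length(missing_genes) > 0L) {
    stop("gene_id(s) absent from the embedding table: ",
         paste(utils::head(missing_genes, 10), collapse = ", "),
         if (length(missing_genes) > 10) sprintf(" (and %d more)", length(missing_genes) - 10) else "")
  }
  drugs <- unique(records[, c("drug_id", "smiles")])
  graphs <- list()
  bad <- character()
  for (i in seq_len(nrow(drugs))) {
    g <- tryCatch(parse_smiles(drugs$smiles[i]), error = function(e) NULL)
    if (is.null(g)) bad <- c(bad, drugs$drug_id[i])
    else graphs[[drugs$drug_id[i]]] <- g
  }
  if (length(bad) > 0L) {
    stop("unparseable SMILES for drug_id(s): ", paste(bad, collapse = ", "))
  }
  samples <- data.frame(
    drug_id = records$drug_id, gene_id = records$gene_id,
    cell_line = records$cell_line, logFC = records$logFC,
    target = step_function(records$logFC, sf),
    label = expr_label(records$logFC, sf$t)
  )
  list(samples = samples, graphs = graphs)
}

# ---- Adam ----------------------------------------------------------------

.adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

.adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# Forward a set of pairs without gradients, in chunks. pairs: data.frame
# with drug_id, gene_id. Returns numeric scores.
.predict_pairs <- function(params, cfg, graphs, embeddings, pairs,
                           chunk = 2000L) {
  out <- numeric(nrow(pairs))
  for (b0 in seq(1L, nrow(pairs), by = chunk)) {
    idx <- b0:min(b0 + chunk - 1L, nrow(pairs))
    sub <- pairs[idx, , drop = FALSE]
    ud <- unique(sub$drug_id)
    bg <- batch_graphs(graphs[ud])
    tape <- ag_tape()
    pn <- .params_as_nodes(tape, params, trainable = FALSE)
    s <- .fwd_actin(tape, pn, cfg, bg,
                    unclass(embeddings)[sub$gene_id, , drop = FALSE],
                    match(sub$drug_id, ud))
    out[idx] <- as.vector(ag_value(s))
  }
  out
}

#' Train one per-cell-line ACTIN model
#'
#' @param records Perturbation records of a single cell line.
#' @param embeddings A `gene_embedding` table covering all genes.
#' @param model_config An [actin_config()].
#' @param tc A [train_config()].
#' @param sf An [sf_params()] for target mapping.
#' @param cell_line Optional label; defaults to the records' cell line.
#' @param verbose Print per-epoch losses.
#' @return List with `model` (a trained `cell_line_model`; its `$split`
#'   holds the instance fold assignment) and `history` (data.frame of
#'   per-epoch train/validation loss).
#' @export
train_cell_line <- function(records, embeddings,
                            model_config = actin_config(),
                            tc = train_config(), sf = sf_params(),
                            cell_line = NULL, verbose = FALSE) {
  cls <- unique(records$cell_line)
  if (length(cls) != 1L) {
    stop("records contain ", length(cls),
         " cell lines (", paste(cls, collapse = ", "),
         "); per-cell-line models are trained on exactly one")
  }
  if (is.null(cell_line)) cell_line <- cls
  built <- build_pairs(records, embeddings, sf)
  samples <- built$samples
  graphs <- built$graphs
  fold <- split_instances(names(graphs), tc$split, seed = tc$seed)
  samples$fold <- fold[samples$drug_id]
  model <- new_cell_line_model(cell_line, model_config, seed = tc$seed)
  cfg <- model$config
  params <- model$params
  emb <- unclass(embeddings)
  tr <- which(samples$fold == "train")
  va <- which(samples$fold == "val")
  has_val <- length(va) > 0L
  adam <- .adam_init(params)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  best_val <- Inf
  best_params <- params
  stall <- 0L
  set.seed(tc$seed + 1L)
  for (ep in seq_len(tc$epochs)) {
    ord <- sample(tr)
    ep_loss <- 0; nb <- 0L
    for (b0 in seq(1L, length(ord), by = tc$batch_size)) {
      idx <- ord[b0:min(b0 + tc$batch_size - 1L, length(ord))]
      sub <- samples[idx, , drop = FALSE]
      ud <- unique(sub$drug_id)
      bg <- batch_graphs(graphs[ud])
      tape <- ag_tape()
      pn <- .params_as_nodes(tape, params, trainable = TRUE)
      s <- .fwd_actin(tape, pn, cfg, bg, emb[sub$gene_id, , drop = FALSE],
                      match(sub$drug_id, ud))
      loss <- ag_smooth_l1(tape, s, matrix(sub$target, ncol = 1L), tc$beta)
      lv <- ag_value(loss)[1, 1]
      if (!is.finite(lv)) {
        stop(sprintf("training diverged (non-finite loss) at epoch %d; try a smaller learning rate (current %g)",
                     ep, tc$lr))
      }
      ag_backward(tape, loss)
      grads <- lapply(pn, function(nd) nd$grad)
      st <- .adam_step(params, grads, adam, tc$lr)
      params <- st$params
      adam <- st$state
      ep_loss <- ep_loss + lv
      nb <- nb + 1L
    }
    train_loss <- ep_loss / nb
    val_loss <- NA_real_
    if (has_val) {
      vp <- .predict_pairs(params, cfg, graphs, embeddings,
                           samples[va, , drop = FALSE])
      val_loss <- smooth_l1(vp, samples$target[va], tc$beta)
      if (val_loss < best_val - 1e-6) {
        best_val <- val_loss
        best_params <- params
        stall <- 0L
      } else {
        stall <- stall + 1L
      }
    }
    history <- rbind(history, data.frame(epoch = ep, train_loss = train_loss,
                                         val_loss = val_loss))
    if (verbose) {
      message(sprintf("epoch %3d  train %.5f  val %s", ep, train_loss,
                      if (is.na(val_loss)) "-" else sprintf("%.5f", val_loss)))
    }
    if (has_val && stall >= tc$patience) break
  }
  model$params <- if (has_val) best_params else params
  model$trained <- TRUE
  model$history <- history
  model$split <- fold
  model$train_config <- unclass(tc)
  list(model = model, history = history)
}

#' Predict scores for a table of (drug, gene) pairs
#'
#' @param model A trained `cell_line_model`.
#' @param pairs Data.frame with `drug_id` and `gene_id`.
#' @param graphs Named list of molecular graphs (per drug_id).
#' @param embeddings A `gene_embedding` table.
#' @return Numeric vector of scores in (-1, 1), one per row of `pairs`.
#' @export
predict_pairs <- function(model, pairs, graphs, embeddings) {
  stopifnot(inherits(model, "cell_line_model"))
  missing_g <- setdiff(unique(pairs$gene_id), rownames(embeddings))
  if (length(missing_g) > 0L) {
    stop("gene_id(s) absent from the embedding table: ",
         paste(missing_g, collapse = ", "))
  }
  missing_d <- setdiff(unique(pairs$drug_id), names(graphs))
  if (length(missing_d) > 0L) {
    stop("no graph for drug_id(s): ", paste(missing_d, collapse = ", "))
  }
  .predict_pairs(model$params, model$config, graphs, embeddings, pairs)
}
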