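# Run configuration and format-exact table IO.
#
# A single YAML file configures the whole pipeline (step function, encoder,
# interfusion, training). Unknown keys are rejected with their full key
# path so typos never silently fall back to defaults. Tables are plain
# UTF-8 TSV with '.' decimals; gene and drug ids are opaque strings.

.config_defaults <- function() {
  list(
    step_function = list(w = 0.1, s1 = 1, s2 = 1, t = 1),
    encoder = list(d = 256, gat_heads = 4, n_gat_stages = 2,
                   pool_ratio = 0.8, leaky_slope = 0.2),
    interfusion = list(heads = 4, n_blocks = 6, ffn_hidden = 0),  # 0 = 4 * d
    training = list(batch_size = 1000, lr = 1e-4, epochs = 50, patience = 10,
                    split = list(train = 0.8, test = 0.2), beta = 1, seed = 1),
    synth = list(n_drugs = 200, n_genes = 100, noise_sd = 0.3, seed = 42),
    embedding = list(dim = 128, walk_length = 80, walks_per_node = 10,
                     window = 5, p = 1, q = 1, epochs = 5)
  )
}

.merge_config <- function(defaults, user, path = character()) {
  for (key in names(user)) {
    kp <- paste(c(path, key), collapse = ".")
    if (!(key %in% names(defaults))) {
      stop("unknown configuration key: ", kp)
    }
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]])) stop("configuration key ", kp, " must be a mapping")
      defaults[[key]] <- .merge_config(defaults[[key]], user[[key]], c(path, key))
    } else {
      val <- user[[key]]
      dflt <- defaults[[key]]
      if (!is.null(dflt) && is.numeric(dflt) && !is.numeric(val)) {
        stop("configuration key ", kp, " must be numeric")
      }
      defaults[[key]] <- val
    }
  }
  defaults
}

.validate_config <- function(cfg) {
  if (cfg$training$batch_size < 1) stop("training.batch_size must be >= 1")
  if (cfg$training$lr <= 0) stop("training.lr must be > 0")
  if (cfg$training$epochs < 1) stop("training.epochs must be >= 1")
  sf <- cfg$step_function
  sf_params(sf$w, sf$s1, sf$s2, sf$t)  # range checks
  if (cfg$encoder$pool_ratio <= 0 || cfg$encoder$pool_ratio > 1) {
    stop("encoder.pool_ratio must lie in (0, 1]")
  }
  if (cfg$interfusion$ffn_hidden < 0) stop("interfusion.ffn_hidden must be >= 0")
  fr <- unlist(cfg$training$split)
  if (abs(sum(fr) - 1) > 1e-8) stop("training.split fractions must sum to 1")
  invisible(cfg)
}

#' Load a run configuration
#'
#' YAML (or JSON) file; missing keys take package defaults, unknown keys
#' are rejected with their key path. An empty file yields all defaults.
#'
#' @param path Config file path, or `NULL` for pure defaults.
#' @return A `run_config`: nested list with sections `step_function`,
#'   `encoder`, `interfusion`, `training`, `synth`, `embedding`, plus a
#'   `config_hash` attribute.
#' @export
load_config <- function(path = NULL) {
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("no such config file: ", path)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
  }
  cfg <- .merge_config(.config_defaults(), user)
  .validate_config(cfg)
  structure(cfg, class = "run_config", config_hash = .config_hash(cfg))
}

#' Write a run configuration to YAML
#'
#' @param cfg A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Convert a run configuration into the model/training objects
#'
#' @param cfg A `run_config`.
#' @return List with `model_config` ([actin_config()]), `tc`
#'   ([train_config()]) and `sf` ([sf_params()]).
#' @export
config_objects <- function(cfg) {
  enc <- cfg$encoder
  itf <- cfg$interfusion
  mc <- actin_config(
    d = enc$d, gat_heads = enc$gat_heads, n_gat_stages = enc$n_gat_stages,
    pool_ratio = enc$pool_ratio, leaky_slope = enc$leaky_slope,
    if_heads = itf$heads, n_blocks = itf$n_blocks,
    ffn_hidden = if (itf$ffn_hidden == 0) 4 * enc$d else itf$ffn_hidden
  )
  tr <- cfg$training
  tc <- train_config(batch_size = tr$batch_size, lr = tr$lr,
                     epochs = tr$epochs, patience = tr$patience,
                     split = unlist(tr$split), beta = tr$beta, seed = tr$seed)
  sfp <- cfg$step_function
  list(model_config = mc, tc = tc, sf = sf_params(sfp$w, sfp$s1, sfp$s2, sfp$t))
}

#' Read a perturbation table
#'
#' TSV with header `drug_id`, `smiles`, `cell_line`, `gene_id`, `logFC`.
#' Duplicate (drug_id, cell_line, gene_id) triples are rejected with their
#' line numbers.
#'
#' @param path File path.
#' @return Data.frame of perturbation records.
#' @export
read_perturbation_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("drug_id", "smiles", "cell_line", "gene_id", "logFC")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0L) {
    stop("perturbation table missing column(s): ", paste(miss, collapse = ", "))
  }
  key <- paste(df$drug_id, df$cell_line, df$gene_id, sep = "\r")
  if (anyDuplicated(key)) {
    ln <- which(duplicated(key) | duplicated(key, fromLast = TRUE)) + 1L
    stop("duplicate (drug_id, cell_line, gene_id) at line(s): ",
         paste(utils::head(ln, 20), collapse = ", "))
  }
  if (any(!is.finite(df$logFC))) stop("logFC values must be finite")
  df[, req]
}

#' Write a perturbation table
#'
#' @param records Perturbation data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_perturbation_table <- function(records, path) {
  utils::write.table(
    records[, c("drug_id", "smiles", "cell_line", "gene_id", "logFC")],
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Write a PPI edge list
#'
#' @param edges Data.frame with `gene_a`, `gene_b`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ppi_edges <- function(edges, path) {
  utils::write.table(edges[, c("gene_a", "gene_b")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
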