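# Signature-reversal drug screening.
#
# Deployment stage: given a disease differential-expression signature and
# a trained per-cell-line model, every library drug's predicted
# transcriptional profile is scored against the SF-mapped signature; drugs
# whose predicted effect most strongly opposes the disease signature rank
# highest (the connectivity-map reversal convention).

#' Read a disease signature table
#'
#' TSV with header `gene_id`, `logFC` (extra columns ignored).
#'
#' @param path File path.
#' @return Named numeric vector of logFC keyed by gene id.
#' @export
read_signature <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "logFC") %in% names(df))) {
    stop("signature table must have columns gene_id and logFC")
  }
  if (anyDuplicated(df$gene_id)) {
    stop("duplicate gene_id in signature: ",
         paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
  }
  if (any(!is.finite(df$logFC))) stop("signature logFC values must be finite")
  stats::setNames(df$logFC, df$gene_id)
}

#' Predict a drug's transcriptional profile
#'
#' One bounded interaction score per requested gene.
#'
#' @param model A trained `cell_line_model`.
#' @param drug A [molecular_graph()] or SMILES string.
#' @param embeddings A `gene_embedding` table.
#' @param genes Gene ids to score (default: all embedded genes).
#' @return Named numeric vector of scores in (-1, 1).
#' @export
predict_profile <- function(model, drug, embeddings,
                            genes = rownames(embeddings)) {
  if (is.character(drug)) drug <- parse_smiles(drug)
  missing_g <- setdiff(genes, rownames(embeddings))
  if (length(missing_g) > 0L) {
    stop("gene_id(s) absent from the embedding table: ",
         paste(missing_g, collapse = ", "))
  }
  pairs <- data.frame(drug_id = "query", gene_id = genes)
  s <- .predict_pairs(model$params, model$config, list(query = drug),
                      embeddings, pairs)
  stats::setNames(s, genes)
}

#' Signature-reversal score of a predicted profile
#'
#' `-Pearson(profile, SF(signature))` over the overlapping genes: +1 means
#' the predicted effect perfectly opposes the disease signature, -1 means
#' it mimics it.
#'
#' @param profile Named score vector from [predict_profile()].
#' @param signature Named logFC vector ([read_signature()]).
#' @param sf An [sf_params()] used to map the signature onto the score
#'   scale.
#' @return Scalar in `[-1, 1]`.
#' @export
reversal_score <- function(profile, signature, sf = sf_params()) {
  genes <- intersect(names(profile), names(signature))
  if (length(genes) < 2L) {
    stop("need at least 2 overlapping genes (found ", length(genes), ")")
  }
  x <- profile[genes]
  y <- step_function(signature[genes], sf)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("reversal score undefined: zero variance over the gene overlap")
  }
  -stats::cor(x, y)
}

#' Rank a drug library against a disease signature
#'
#' @param model A trained `cell_line_model`.
#' @param library Data.frame with `drug_id` and `smiles` (non-empty).
#' @param signature Named logFC vector.
#' @param embeddings A `gene_embedding` table.
#' @param top_k Number of candidates to return (default: whole library).
#' @param sf An [sf_params()].
#' @param drop_missing_genes Drop signature genes absent from the
#'   embedding table (with a message) instead of erroring.
#' @return Data.frame `drug_id`, `score`, sorted descending by score
#'   (ties broken by drug_id).
#' @export
rank_candidates <- function(model, library, signature, embeddings,
                            top_k = nrow(library), sf = sf_params(),
                            drop_missing_genes = FALSE) {
  if (nrow(library) == 0L) stop("drug library is empty")
  genes <- names(signature)
  absent <- setdiff(genes, rownames(embeddings))
  if (length(absent) > 0L) {
    if (!drop_missing_genes) {
      stop(length(absent), " signature gene(s) absent from the embedding table: ",
           paste(utils::head(absent, 10), collapse = ", "))
    }
    message("dropping ", length(absent), " signature gene(s) without embeddings")
    genes <- setdiff(genes, absent)
  }
  scores <- vapply(seq_len(nrow(library)), function(i) {
    prof <- predict_profile(model, library$smiles[i], embeddings, genes)
    reversal_score(prof, signature, sf)
  }, numeric(1))
  ord <- order(-scores, library$drug_id)
  out <- data.frame(drug_id = library$drug_id[ord], score = scores[ord])
  utils::head(out, min(top_k, nrow(out)))
}
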