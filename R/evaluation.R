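# Test-set metrics and cross-model aggregation.
#
# Up- and down-regulation are scored as two one-vs-rest ranking problems
# (ROC-AUC in Mann-Whitney form, PR-AUC as average precision), predicted
# and observed expression are compared with per-instance Pearson
# correlation, and the three-way Up/Down/None confusion matrix yields an
# error rate counting completely opposite calls. Per-cell-line reports are
# combined by a sample-size-weighted mean.

#' ROC-AUC (Mann-Whitney form)
#'
#' Probability that a random positive outranks a random negative; ties
#' receive half credit. Computed from ranks, so it equals all-pairs
#' concordance counting.
#'
#' @param labels Binary vector (logical or 0/1); both classes required.
#' @param scores Numeric scores, higher = more positive.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(labels, scores) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) {
    stop("ROC-AUC undefined: need both positive and negative labels")
  }
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' PR-AUC (average precision)
#'
#' Step-interpolated area under the precision-recall curve: the mean of
#' the precision at each positive, taken in descending score order
#' (stable, so tied scores keep their input order).
#'
#' @param labels Binary vector with at least one positive.
#' @param scores Numeric scores.
#' @return Average precision in `[0, 1]`.
#' @export
pr_auc <- function(labels, scores) {
  labels <- as.logical(labels)
  if (sum(labels) == 0L) stop("PR-AUC undefined: no positive labels")
  ord <- order(-scores)
  lab <- labels[ord]
  tp <- cumsum(lab)
  prec <- tp / seq_along(lab)
  sum(prec[lab]) / sum(lab)
}

#' Build the Up and Down ranking problems
#'
#' The Up problem marks true-Up samples positive with score `s_hat`; the
#' Down problem marks true-Down samples positive with score `-s_hat`.
#'
#' @param labels Factor of true labels (`Down`/`None`/`Up`).
#' @param scores Predicted scores, aligned with `labels`.
#' @return List of two lists `up` and `down`, each with `labels`, `scores`.
#' @export
up_down_scores <- function(labels, scores) {
  if (length(labels) != length(scores)) {
    stop("labels and scores must have equal length")
  }
  list(up = list(labels = labels == "Up", scores = scores),
       down = list(labels = labels == "Down", scores = -scores))
}

#' Mean per-instance Pearson correlation
#'
#' Pearson r between predictions and targets computed within each
#' perturbation instance (over its genes), then averaged (unweighted)
#' across instances. Zero-variance instances are excluded with a warning.
#'
#' @param instance Instance id per sample (e.g. drug_id).
#' @param predictions Predicted scores.
#' @param targets SF-mapped observed values.
#' @param pooled If TRUE, return a single pooled correlation instead.
#' @return Mean correlation (scalar).
#' @export
pearson_per_instance <- function(instance, predictions, targets,
                                 pooled = FALSE) {
  if (pooled) return(stats::cor(predictions, targets))
  rs <- vapply(split(seq_along(instance), instance), function(ix) {
    if (length(ix) < 2L || stats::sd(targets[ix]) == 0 ||
        stats::sd(predictions[ix]) == 0) return(NA_real_)
    stats::cor(predictions[ix], targets[ix])
  }, numeric(1))
  n_bad <- sum(is.na(rs))
  if (n_bad > 0L) {
    warning(n_bad, " instance(s) excluded (fewer than 2 genes or zero variance)")
  }
  mean(rs, na.rm = TRUE)
}

#' Confusion matrix and opposite-call error rate
#'
#' Predicted labels come from [predicted_label()]. The error rate is the
#' fraction of completely opposite calls (predicted Up on a true Down, or
#' predicted Down on a true Up); by default the denominator is the number
#' of test pairs whose true label is Up or Down, switchable to all pairs.
#'
#' @param true_labels Factor of true labels.
#' @param scores Predicted scores.
#' @param sf An [sf_params()].
#' @param denominator `"updown"` (default) or `"all"`.
#' @return List with `confusion` (3x3 table, prediction x truth) and
#'   `error_rate`.
#' @export
confusion_and_error <- function(true_labels, scores, sf = sf_params(),
                                denominator = c("updown", "all")) {
  denominator <- match.arg(denominator)
  if (length(true_labels) != length(scores)) {
    stop("labels and scores must have equal length")
  }
  pred <- predicted_label(scores, sf)
  cm <- table(prediction = pred, truth = factor(true_labels,
                                                levels = c("Down", "None", "Up")))
  opposite <- cm["Up", "Down"] + cm["Down", "Up"]
  denom <- if (denominator == "updown") {
    sum(cm[, "Up"]) + sum(cm[, "Down"])
  } else {
    sum(cm)
  }
  if (denom == 0L) stop("error rate undefined: no Up/Down truths")
  list(confusion = cm, error_rate = as.numeric(opposite) / denom)
}

#' Sample-size-weighted aggregation of per-model metrics
#'
#' Weighted mean `sum(w v) / sum(w)` rounded to 4 decimals, with the
#' unweighted standard deviation reported alongside (labelled as such:
#' whether published spreads are weighted is generally unstated).
#'
#' @param values Numeric metric values, one per model.
#' @param weights Positive sample sizes, same length.
#' @return List with `mean` (weighted, 4 dp), `sd_unweighted`, `n_total`.
#' @export
weighted_aggregate <- function(values, weights) {
  if (length(values) != length(weights)) {
    stop("values and weights must have equal length")
  }
  if (any(weights <= 0) || sum(weights) == 0) {
    stop("weights must be positive with a nonzero total")
  }
  list(mean = round(sum(weights * values) / sum(weights), 4),
       sd_unweighted = stats::sd(values),
       n_total = sum(weights))
}

#' Evaluate a trained model on held-out perturbation records
#'
#' @param model A trained `cell_line_model` (with `$split` from training).
#' @param records Perturbation records (typically the full table; rows are
#'   filtered to the model's test fold when `fold = "test"`).
#' @param embeddings A `gene_embedding` table.
#' @param sf An [sf_params()].
#' @param fold Which fold of `model$split` to evaluate (`"test"` default),
#'   or `NULL` to use all records.
#' @return An evaluation report: list with `cell_line`, `n_instances`,
#'   `n_pairs`, `roc_auc_down`, `pr_auc_down`, `roc_auc_up`, `pr_auc_up`,
#'   `mean_pearson`, `confusion`, `error_rate`, and the per-pair `scores`.
#' @export
evaluate_cell_line_model <- function(model, records, embeddings,
                                     sf = sf_params(), fold = "test") {
  stopifnot(inherits(model, "cell_line_model"))
  if (!is.null(fold)) {
    if (is.null(model$split)) stop("model carries no split; pass fold = NULL")
    keep_drugs <- names(model$split)[model$split == fold]
    records <- records[records$drug_id %in% keep_drugs, , drop = FALSE]
    if (nrow(records) == 0L) stop("no records in fold '", fold, "'")
  }
  built <- build_pairs(records, embeddings, sf)
  s <- predict_pairs(model, built$samples, built$graphs, embeddings)
  lab <- built$samples$label
  ud <- up_down_scores(lab, s)
  ce <- confusion_and_error(lab, s, sf)
  list(
    cell_line = model$cell_line,
    n_instances = length(unique(built$samples$drug_id)),
    n_pairs = nrow(built$samples),
    roc_auc_down = roc_auc(ud$down$labels, ud$down$scores),
    pr_auc_down = pr_auc(ud$down$labels, ud$down$scores),
    roc_auc_up = roc_auc(ud$up$labels, ud$up$scores),
    pr_auc_up = pr_auc(ud$up$labels, ud$up$scores),
    mean_pearson = pearson_per_instance(built$samples$drug_id, s,
                                        built$samples$target),
    confusion = ce$confusion,
    error_rate = ce$error_rate,
    scores = s,
    labels = lab,
    targets = built$samples$target,
    instance = built$samples$drug_id
  )
}

#' Published per-cell-line ACTIN test metrics
#'
#' The test metrics and sample sizes published for the ten per-cell-line
#' ACTIN models trained on LINCS L1000 data. Used to reproduce the
#' sample-size-weighted "ACTIN-ALL" aggregation; the package does not
#' retrain these models.
#'
#' @return Data.frame with columns `cell_line`, `n`, `roc_auc_down`,
#'   `pr_auc_down`, `roc_auc_up`, `pr_auc_up`.
#' @export
actin_reference_metrics <- function() {
  data.frame(
    cell_line = c("VCAP", "PC3", "YAPC", "MCF7", "HT29", "HELA", "HCC515",
                  "HA1E", "A549", "A375"),
    n = c(349, 601, 140, 758, 385, 172, 299, 480, 285, 492),
    roc_auc_down = c(0.7623, 0.7721, 0.7651, 0.7939, 0.7536, 0.7306,
                     0.7189, 0.7646, 0.7548, 0.7963),
    pr_auc_down = c(0.8550, 0.8689, 0.8378, 0.8782, 0.8397, 0.8337,
                    0.8269, 0.8457, 0.8881, 0.8704),
    roc_auc_up = c(0.7191, 0.7612, 0.7318, 0.7758, 0.7195, 0.6782,
                   0.7021, 0.7423, 0.7074, 0.7687),
    pr_auc_up = c(0.5101, 0.5895, 0.5464, 0.6123, 0.5684, 0.4739,
                  0.5416, 0.5906, 0.5024, 0.6228)
  )
}
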