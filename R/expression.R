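# Mapping log fold changes to bounded interaction targets.
#
# Raw logFC values are squashed into (-1, 1) by a three-interval "step
# function" (SF): a modified tanh that damps the biologically uninteresting
# band |logFC| < t and saturates toward +/-1 beyond it, so the regression
# target emphasizes genes with substantial expression change. Class labels
# (Up / Down / None) use the same threshold t on the raw logFC scale.

#' Step-function parameters
#'
#' @param w Inner weight in (0, 1): the value the SF approaches at the
#'   threshold (`SF(t) = w * tanh(s1 * t)`); small w flattens the inner band.
#' @param s1 Inner gain (> 0) applied inside `[-t, t]`.
#' @param s2 Outer gain (> 0) controlling how fast the SF saturates past t.
#' @param t Threshold in logFC units (> 0, default 1: the conventional
#'   two-fold-change cut).
#' @return An object of class `sf_params`.
#' @export
sf_params <- function(w = 0.1, s1 = 1, s2 = 1, t = 1) {
  if (!is.numeric(w) || w <= 0 || w >= 1) stop("w must lie in (0, 1)")
  if (!is.numeric(s1) || s1 <= 0) stop("s1 must be > 0")
  if (!is.numeric(s2) || s2 <= 0) stop("s2 must be > 0")
  if (!is.numeric(t) || t <= 0) stop("t must be > 0")
  structure(list(w = w, s1 = s1, s2 = s2, t = t), class = "sf_params")
}

#' The step function SF: map logFC into (-1, 1)
#'
#' Piecewise odd map: `SF(x) = w * tanh(s1 * x)` for `|x| <= t`, and
#' `SF(x) = sign(x) * (w * tanh(s1 * t) + (1 - w * tanh(s1 * t)) *
#' tanh(s2 * (|x| - t)))` beyond the threshold. Continuous, strictly
#' increasing, odd, bounded in (-1, 1): values inside the dead band map
#' near zero while |logFC| > t saturates toward +/-1.
#'
#' @param x Numeric vector of logFC values (finite).
#' @param params An [sf_params()].
#' @return Numeric vector of the same length, in (-1, 1).
#' @export
step_function <- function(x, params = sf_params()) {
  if (!is.numeric(x) || any(!is.finite(x))) stop("logFC values must be finite")
  p <- params
  edge <- p$w * tanh(p$s1 * p$t)
  inner <- p$w * tanh(p$s1 * x)
  outer <- sign(x) * (edge + (1 - edge) * tanh(p$s2 * (abs(x) - p$t)))
  ifelse(abs(x) <= p$t, inner, outer)
}

#' Up / Down / None label of a raw logFC value
#'
#' Strict threshold comparison: `Up` iff `logFC > t`, `Down` iff
#' `logFC < -t`, otherwise `None` (values exactly at +/-t are `None`).
#'
#' @param x Numeric vector of logFC values (finite).
#' @param t Threshold (default 1).
#' @return Factor with levels `Down`, `None`, `Up`.
#' @export
expr_label <- function(x, t = 1) {
  if (!is.numeric(x) || any(!is.finite(x))) stop("logFC values must be finite")
  factor(ifelse(x > t, "Up", ifelse(x < -t, "Down", "None")),
         levels = c("Down", "None", "Up"))
}

#' Label of a predicted interaction score
#'
#' Thresholds on the SF scale so that `predicted_label(step_function(x))`
#' agrees with `expr_label(x)` away from the exact thresholds: `Up` iff
#' `s_hat > SF(t)`, `Down` iff `s_hat < SF(-t)`, else `None`.
#'
#' @param s_hat Numeric vector of predicted scores in (-1, 1).
#' @param params An [sf_params()].
#' @return Factor with levels `Down`, `None`, `Up`.
#' @export
predicted_label <- function(s_hat, params = sf_params()) {
  if (!is.numeric(s_hat) || any(!is.finite(s_hat))) {
    stop("predicted scores must be finite")
  }
  edge <- params$w * tanh(params$s1 * params$t)
  factor(ifelse(s_hat > edge, "Up", ifelse(s_hat < -edge, "Down", "None")),
         levels = c("Down", "None", "Up"))
}
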