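#' Two-step (global then local) inflection cutoff for a factor signal
#'
#' Ranks the scores ascending, finds the global inflection cutoff, then
#' recomputes a local inflection point on the lower portion of the curve
#' (scores at or below the global cutoff) using the global cutoff value as
#' the new maximum in the reference slope. The local cutoff is the returned
#' prediction threshold; scores strictly above it are predicted positives.
#' The local cutoff never exceeds the global one.
#'
#' @param scores Numeric vector (factor signal per enhancer, zeros for
#'   unbound enhancers), length >= 3.
#' @param half_window Central-difference half-window for [find_inflection()].
#' @return A list with `cutoff_value` (the local cutoff), `global_cutoff`,
#'   `cutoff_rank`, `ref_slope`, `n_predicted` (scores strictly above the
#'   cutoff).
#' @export
two_step_cutoff <- function(scores, half_window = 1) {
  res <- find_inflection(scores, mode = "local", half_window = half_window)
  list(
    cutoff_value = res$cutoff_value,
    global_cutoff = res$global_cutoff %||% res$cutoff_value,
    cutoff_rank = res$cutoff_rank,
    ref_slope = res$ref_slope,
    n_predicted = sum(scores > res$cutoff_value)
  )
}

#' ROC evaluation of a score against a binary truth
#'
#' Sweeps thresholds over the unique score values (descending, ties grouped
#' into one step), computes the ROC curve and its trapezoidal AUC
#' (equivalently the tie-adjusted Mann-Whitney statistic), and reports the
#' true/false positive rates at a supplied cutoff with strict `>` defining a
#' positive call.
#'
#' @param score Numeric vector of predictor scores.
#' @param truth Logical vector, same length; must contain both classes.
#' @param cutoff Score cutoff at which TPR/FPR are reported (e.g. from
#'   [two_step_cutoff()]). Default: the two-step cutoff of `score`.
#' @return An object of class `prediction_eval`: list with `auc`,
#'   `roc_points` (tibble `threshold`, `fpr`, `tpr`, beginning at (0,0) and
#'   ending at (1,1)), `cutoff_value`, `tpr_at_cutoff`, `fpr_at_cutoff`,
#'   `n_pos`, `n_neg`.
#' @export
roc_evaluate <- function(score, truth, cutoff = NULL) {
  stopifnot(length(score) == length(truth), is.logical(truth))
  if (anyNA(score) || anyNA(truth) || any(!is.finite(score))) {
    abort("scores and truth must be finite and non-missing")
  }
  n_pos <- sum(truth)
  n_neg <- sum(!truth)
  if (n_pos == 0 || n_neg == 0) {
    abort("truth must contain both positive and negative labels")
  }
  cutoff <- cutoff %||% two_step_cutoff(score)$cutoff_value

  ord <- order(score, decreasing = TRUE)
  s <- score[ord]
  t <- truth[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(t)
  fp <- cumsum(!t)
  last <- which(!duplicated(grp, fromLast = TRUE))
  roc <- tibble(
    threshold = c(Inf, s[last]),
    fpr = c(0, fp[last] / n_neg),
    tpr = c(0, tp[last] / n_pos)
  )
  auc <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)

  structure(
    list(
      auc = auc,
      roc_points = roc,
      cutoff_value = cutoff,
      tpr_at_cutoff = sum(truth & score > cutoff) / n_pos,
      fpr_at_cutoff = sum(!truth & score > cutoff) / n_neg,
      n_pos = n_pos,
      n_neg = n_neg
    ),
    class = "prediction_eval"
  )
}

#' @export
print.prediction_eval <- function(x, ...) {
  cat(sprintf(
    "<prediction_eval> AUC %.4f; at cutoff %.4g: TPR %.3f, FPR %.3f (%d pos / %d neg)\n",
    x$auc, x$cutoff_value, x$tpr_at_cutoff, x$fpr_at_cutoff, x$n_pos, x$n_neg
  ))
  invisible(x)
}

#' Combine two factor signals into one predictor score
#'
#' Each signal is min-max normalized over the enhancer universe (constant
#' signals normalize to all-zero) and then combined: by sum (default),
#' elementwise minimum, or product.
#'
#' @param signal_a,signal_b Numeric vectors over the same enhancer universe.
#' @param mode `"sum"`, `"min"` or `"product"`.
#' @return Numeric vector of combined scores.
#' @export
combine_factors <- function(signal_a, signal_b, mode = c("sum", "min", "product")) {
  mode <- match.arg(mode)
  if (length(signal_a) != length(signal_b)) {
    abort("signal_a and signal_b must cover the same enhancer universe")
  }
  m <- minmax_columns(cbind(signal_a, signal_b))
  switch(mode,
    sum = m[, 1] + m[, 2],
    min = pmin(m[, 1], m[, 2]),
    product = m[, 1] * m[, 2]
  )
}

#' Rank-based prediction of high-occupancy enhancers from factor signals
#'
#' Convenience wrapper reproducing the signal-ranking predictor: extracts
#' the per-enhancer signal of one factor (or the combination of two), finds
#' the two-step cutoff, and evaluates prediction of the aSE/dSE classes by
#' ROC.
#'
#' @param enhancers Active-enhancer tibble.
#' @param factor_peaks Peak tibble of the predictor factor (e.g. DNase).
#' @param truth Logical vector: TRUE for enhancers in the positive class
#'   (aSE or dSE), aligned with `enhancers` rows.
#' @param factor_peaks2 Optional second factor to combine with the first.
#' @param combine `"sum"`, `"min"` or `"product"` (used when `factor_peaks2`
#'   is given).
#' @return A `prediction_eval` (see [roc_evaluate()]) with an extra element
#'   `score` holding the per-enhancer predictor score.
#' @export
predict_high_occupancy <- function(enhancers, factor_peaks, truth,
                                   factor_peaks2 = NULL,
                                   combine = c("sum", "min", "product")) {
  combine <- match.arg(combine)
  score <- enhancer_signal(enhancers, factor_peaks)
  if (!is.null(factor_peaks2)) {
    score <- combine_factors(score, enhancer_signal(enhancers, factor_peaks2),
                             mode = combine)
  }
  ev <- roc_evaluate(score, truth, cutoff = two_step_cutoff(score)$cutoff_value)
  ev$score <- score
  ev
}

# per-enhancer signal of one factor: max signal of overlapping peaks, 0 if none
enhancer_signal <- function(enhancers, peaks) {
  hits <- overlap_pairs(enhancers, peaks, window_bp = 0)
  out <- numeric(nrow(enhancers))
  if (nrow(hits) > 0) {
    agg <- vapply(split(peaks$signal_value[hits$idx_b], hits$idx_a), max, numeric(1))
    out[as.integer(names(agg))] <- agg
  }
  out
}
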