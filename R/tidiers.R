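#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a signal matrix into long form
#'
#' @param x A `signal_matrix`.
#' @param ... Unused.
#' @return A long tibble: `enhancer_id`, `factor`, `raw`, `normalized`,
#'   `bound`.
#' @method tidy signal_matrix
#' @export
tidy.signal_matrix <- function(x, ...) {
  tibble(
    enhancer_id = rep(x$enhancer_ids, times = length(x$factors)),
    factor = rep(x$factors, each = length(x$enhancer_ids)),
    raw = as.vector(x$raw),
    normalized = as.vector(x$normalized),
    bound = as.vector(x$raw > 0)
  )
}

#' @rdname tidy.signal_matrix
#' @method glance signal_matrix
#' @export
glance.signal_matrix <- function(x, ...) {
  tibble(
    n_enhancers = length(x$enhancer_ids),
    n_factors = length(x$factors),
    frac_bound = mean(x$raw > 0)
  )
}

#' Tidy a classic-SE call into its ranked region table
#'
#' @param x A `classic_se_call`.
#' @param ... Unused.
#' @return The region tibble (without the list column of member indices).
#' @method tidy classic_se_call
#' @export
tidy.classic_se_call <- function(x, ...) {
  select(x$regions, -"member_idx")
}

#' @rdname tidy.classic_se_call
#' @method glance classic_se_call
#' @export
glance.classic_se_call <- function(x, ...) {
  tibble(
    n_regions = nrow(x$regions),
    n_se = sum(x$regions$is_se),
    cutoff_signal = x$cutoff_signal,
    stitch_distance = x$stitch_distance
  )
}

#' One-row summary of an enhancer classification
#'
#' @param x An `enhancer_classes` tibble.
#' @param ... Unused.
#' @return A one-row tibble with the class counts, their percentages and the
#'   OS cutoff.
#' @method glance enhancer_classes
#' @export
glance.enhancer_classes <- function(x, ...) {
  tab <- table(x$class)
  tibble(
    n_enhancers = nrow(x),
    n_aSE = as.integer(tab[["aSE"]]),
    n_dSE = as.integer(tab[["dSE"]]),
    n_cSE = as.integer(tab[["cSE"]]),
    n_rEh = as.integer(tab[["rEh"]]),
    pct_high = 100 * mean(x$class %in% c("aSE", "dSE")),
    cutoff_os = attr(x, "cutoff_os")
  )
}

#' Tidy a prediction evaluation into its ROC points
#'
#' @param x A `prediction_eval`.
#' @param ... Unused.
#' @return The ROC tibble (`threshold`, `fpr`, `tpr`).
#' @method tidy prediction_eval
#' @export
tidy.prediction_eval <- function(x, ...) {
  x$roc_points
}

#' @rdname tidy.prediction_eval
#' @method glance prediction_eval
#' @export
glance.prediction_eval <- function(x, ...) {
  tibble(
    auc = x$auc,
    cutoff_value = x$cutoff_value,
    tpr_at_cutoff = x$tpr_at_cutoff,
    fpr_at_cutoff = x$fpr_at_cutoff,
    n_pos = x$n_pos,
    n_neg = x$n_neg
  )
}
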