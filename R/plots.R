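#' Hockey-stick plot of a classic-SE call
#'
#' Ranked total H3K27ac signal per stitched region with the inflection
#' cutoff; regions above the cutoff are the classic super-enhancers.
#'
#' @param object A `classic_se_call`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot classic_se_call
#' @export
autoplot.classic_se_call <- function(object, ...) {
  df <- arrange(object$regions, .data$total_signal) |>
    mutate(rank = row_number())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$total_signal,
                                   colour = .data$is_se)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = object$cutoff_signal, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "firebrick"),
                                 name = "classic SE") +
    ggplot2::labs(x = "stitched regions ranked by total H3K27ac signal",
                  y = "total signal",
                  title = "ROSE-style classic super-enhancer call")
}

#' Ranked occupancy-score curve coloured by enhancer class
#'
#' @param object An `enhancer_classes` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot enhancer_classes
#' @export
autoplot.enhancer_classes <- function(object, ...) {
  df <- as_tibble(object) |> arrange(.data$os) |> mutate(r = row_number())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r, y = .data$os, colour = .data$class)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = attr(object, "cutoff_os"), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(aSE = "firebrick", dSE = "darkorange",
                                            cSE = "steelblue", rEh = "grey60")) +
    ggplot2::labs(x = "enhancers ranked by occupancy score",
                  y = "occupancy score OS(E)",
                  title = "Occupancy-score curve and inflection cutoff")
}

#' ROC curve of a prediction evaluation
#'
#' @param object A `prediction_eval`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot prediction_eval
#' @export
autoplot.prediction_eval <- function(object, ...) {
  ggplot2::ggplot(object$roc_points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::annotate("point", x = object$fpr_at_cutoff, y = object$tpr_at_cutoff,
                      colour = "firebrick", size = 2) +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("ROC (AUC = %.3f)", object$auc))
}

#' Boxplots of cluster metrics by enhancer-class label
#'
#' @param clusters Output of [classify_clusters()].
#' @param metric One of `span_bp`, `contacts_total`, `n_loops`,
#'   `enhancer_count`, `max_target_fpkm`.
#' @return A ggplot.
#' @export
plot_cluster_metric <- function(clusters, metric = "contacts_total") {
  labels <- c("aSE", "dSE", "cSE", "rEh")
  long <- list_rbind(map(labels, function(lbl) {
    sub <- clusters[clusters[[paste0("contains_", lbl)]], , drop = FALSE]
    tibble(label = lbl, value = as.numeric(sub[[metric]]))
  }))
  long <- filter(long, !is.na(.data$value))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$label, y = .data$value,
                                     fill = .data$label)) +
    ggplot2::geom_boxplot(outlier.size = 0.5, show.legend = FALSE) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "cluster label (non-exclusive)", y = metric,
                  title = sprintf("%s by cluster label", metric))
}
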