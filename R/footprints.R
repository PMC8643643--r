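#' Filter cell-type footprints against a consensus set
#'
#' Keeps a cell-type footprint only when it overlaps (at least 1 bp) an
#' interval of the high-confidence consensus footprint set; adjacency without
#' shared bases does not count.
#'
#' @param footprints Footprint tibble ([read_footprints()] layout; one row
#'   per motif match, grouped by `footprint_id`).
#' @param consensus Interval tibble with `chrom`, `start`, `end`.
#' @return The subset of `footprints` whose footprint overlaps the consensus.
#' @export
filter_consensus <- function(footprints, consensus) {
  fp_iv <- distinct(footprints, .data$footprint_id, .data$chrom, .data$start, .data$end)
  keep <- fp_iv$footprint_id[overlaps_any(fp_iv, consensus, window_bp = 0)]
  filter(footprints, .data$footprint_id %in% keep)
}

#' Assign each footprint to one DNA-binding-domain family
#'
#' A footprint with several matched motifs takes the DBD family of the match
#' with the highest bitscore; exact bitscore ties break to the
#' lexicographically smallest family name so the assignment is deterministic.
#'
#' @param footprints Footprint tibble (one row per motif match).
#' @return A tibble with one row per footprint: `footprint_id`, `chrom`,
#'   `start`, `end`, `dbd_family` (NA when the footprint has no motif match),
#'   `best_bitscore`.
#' @export
assign_dbd <- function(footprints) {
  if (nrow(footprints) == 0) {
    return(tibble(
      footprint_id = character(), chrom = character(), start = integer(),
      end = integer(), dbd_family = character(), best_bitscore = numeric()
    ))
  }
  footprints |>
    group_by(.data$footprint_id, .data$chrom, .data$start, .data$end) |>
    arrange(dplyr::desc(.data$bitscore), .data$dbd_family, .by_group = TRUE) |>
    summarise(
      dbd_family = dplyr::first(.data$dbd_family),
      best_bitscore = dplyr::first(.data$bitscore),
      .groups = "drop"
    ) |>
    arrange(.data$chrom, .data$start, .data$end)
}

#' Per-enhancer footprint statistics
#'
#' Assigns footprints to enhancers by overlap (a footprint straddling two
#' enhancers counts in both; widths are the footprint's own width, never
#' clipped to the enhancer) and summarises, per enhancer: footprint count,
#' widths, gaps between consecutive footprints (ordered by start;
#' edge-to-edge distance floored at 0 for overlapping footprints), best
#' bitscores and the set of DBD families present.
#'
#' @param enhancers Active-enhancer tibble with `enhancer_id`.
#' @param footprints Footprint tibble, ideally consensus-filtered
#'   ([filter_consensus()]).
#' @param gap_measure `"edge"` (default) for next start minus previous end,
#'   or `"midpoint"` for distance between footprint midpoints.
#' @return A tibble with one row per enhancer: `enhancer_id`, `n_footprints`,
#'   list columns `widths`, `gaps`, `best_bitscores`, `dbd_families`, and the
#'   scalar summaries `mean_width`, `mean_gap`, `mean_bitscore`.
#' @export
footprint_stats <- function(enhancers, footprints,
                            gap_measure = c("edge", "midpoint")) {
  gap_measure <- match.arg(gap_measure)
  fp <- assign_dbd(footprints)
  hits <- overlap_pairs(enhancers, fp, window_bp = 0)

  per_enh <- map(seq_len(nrow(enhancers)), function(i) {
    rows <- fp[hits$idx_b[hits$idx_a == i], , drop = FALSE]
    rows <- arrange(rows, .data$start, .data$end)
    n <- nrow(rows)
    widths <- rows$end - rows$start
    gaps <- if (n >= 2) {
      if (gap_measure == "edge") {
        pmax(rows$start[-1] - rows$end[-n], 0)
      } else {
        abs((rows$start[-1] + rows$end[-1]) / 2 - (rows$start[-n] + rows$end[-n]) / 2)
      }
    } else {
      numeric(0)
    }
    mean_width <- if (n) mean(widths) else NA_real_
    mean_gap <- if (n >= 2) mean(gaps) else NA_real_
    mean_bitscore <- if (n && any(!is.na(rows$best_bitscore))) {
      mean(rows$best_bitscore, na.rm = TRUE)
    } else {
      NA_real_
    }
    tibble(
      enhancer_id = enhancers$enhancer_id[i],
      n_footprints = n,
      widths = list(widths),
      gaps = list(gaps),
      best_bitscores = list(rows$best_bitscore),
      dbd_families = list(sort(unique(rows$dbd_family[!is.na(rows$dbd_family)]))),
      mean_width = mean_width,
      mean_gap = mean_gap,
      mean_bitscore = mean_bitscore
    )
  })
  list_rbind(per_enh)
}

#' Annotate direct / indirect / unbound TF binding at enhancers
#'
#' A TF is bound at an enhancer when one of its ChIP-seq peaks overlaps the
#' enhancer. Binding is direct when the enhancer carries a footprint whose
#' assigned DBD family matches the TF's family, otherwise indirect. A TF with
#' unknown DBD family can never be called direct (all bound enhancers are
#' annotated indirect, with a warning).
#'
#' @param tf_peaks Peak tibble for one TF.
#' @param tf_label TF name.
#' @param tf_dbd The TF's DBD family (string, or NA when unknown).
#' @param enhancers Active-enhancer tibble with `enhancer_id`.
#' @param fp_stats Output of [footprint_stats()] for the same enhancers
#'   (supplies the per-enhancer DBD family sets).
#' @return A tibble with one row per enhancer: `tf`, `enhancer_id`, `bound`,
#'   `mode` in `{direct, indirect, unbound}`.
#' @export
annotate_binding <- function(tf_peaks, tf_label, tf_dbd, enhancers, fp_stats) {
  stopifnot(identical(enhancers$enhancer_id, fp_stats$enhancer_id))
  bound <- overlaps_any(enhancers, tf_peaks, window_bp = 0)
  if (is.na(tf_dbd) || !nzchar(tf_dbd)) {
    warn(sprintf("TF '%s' has no DBD family; bound enhancers annotated as indirect", tf_label))
    has_motif <- rep(FALSE, nrow(enhancers))
  } else {
    has_motif <- map_lgl(fp_stats$dbd_families, function(fams) tf_dbd %in% fams)
  }
  tibble(
    tf = tf_label,
    enhancer_id = enhancers$enhancer_id,
    bound = bound,
    mode = case_when(
      !bound ~ "unbound",
      has_motif ~ "direct",
      TRUE ~ "indirect"
    )
  )
}

#' Call anchoring TFs per enhancer class
#'
#' An anchoring TF of a class binds more than 50% of the class's enhancer
#' peaks (by ChIP-seq) AND carries its canonical motif footprint in more than
#' 50% of those bound peaks (direct binding). Both thresholds are strict.
#'
#' @param annotations Binding annotations ([annotate_binding()] rows for one
#'   or more TFs, bound together).
#' @param classes An `enhancer_classes` tibble from [classify_enhancers()]
#'   (or any tibble with `enhancer_id` and `class`).
#' @return A tibble with one row per (tf, class) for classes with at least
#'   one enhancer: `tf`, `class`, `n_class`, `pct_peaks_bound`,
#'   `pct_bound_with_motif`, `is_anchor`. Empty classes are skipped with a
#'   warning.
#' @export
call_anchoring_tfs <- function(annotations, classes) {
  class_tab <- tibble(enhancer_id = classes$enhancer_id, class = as.character(classes$class))
  empty <- setdiff(c("aSE", "dSE", "cSE", "rEh"), unique(class_tab$class))
  if (length(empty) > 0) {
    warn(paste0("empty enhancer class(es) skipped: ", paste(empty, collapse = ", ")))
  }
  annotations |>
    left_join(class_tab, by = "enhancer_id") |>
    filter(!is.na(.data$class)) |>
    group_by(.data$tf, .data$class) |>
    summarise(
      n_class = n(),
      n_bound = sum(.data$bound),
      n_direct = sum(.data$mode == "direct"),
      .groups = "drop"
    ) |>
    mutate(
      pct_peaks_bound = 100 * .data$n_bound / .data$n_class,
      pct_bound_with_motif = ifelse(.data$n_bound > 0, 100 * .data$n_direct / .data$n_bound, 0),
      is_anchor = .data$pct_peaks_bound > 50 & .data$pct_bound_with_motif > 50
    ) |>
    select("tf", "class", "n_class", "pct_peaks_bound", "pct_bound_with_motif", "is_anchor")
}
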