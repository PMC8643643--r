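#' Build the enhancer-by-factor signal matrix
#'
#' For each active enhancer and each TF/cofactor ChIP-seq peak set, records
#' the peak signal at that enhancer (0 when the factor has no overlapping
#' peak) and min-max normalizes each factor column to `[0, 1]`. Histone-mark
#' peak sets should not be included: the occupancy score is defined over TFs
#' and cofactors only.
#'
#' @param enhancers Active-enhancer tibble (needs `chrom`, `start`, `end`,
#'   `enhancer_id`).
#' @param factor_peaks Named list of peak tibbles, one per factor; names are
#'   the factor labels and must be unique.
#' @param aggregate How to combine several peaks of one factor overlapping
#'   one enhancer: `"max"` (default; robust to peak fragmentation), `"sum"`
#'   or `"mean"`.
#' @return An object of class `signal_matrix`: list with `enhancer_ids`,
#'   `factors`, `raw` and `normalized` (both enhancers x factors matrices).
#'   Constant raw columns (including all-zero) normalize to all-zero.
#' @export
build_signal_matrix <- function(enhancers, factor_peaks,
                                aggregate = c("max", "sum", "mean")) {
  aggregate <- match.arg(aggregate)
  stopifnot(is.list(factor_peaks), length(factor_peaks) >= 1)
  labels <- names(factor_peaks)
  if (is.null(labels) || any(labels == "") || anyDuplicated(labels)) {
    abort("factor_peaks must be a named list with unique, non-empty labels")
  }
  if (!"enhancer_id" %in% names(enhancers)) {
    abort("enhancers must carry an enhancer_id column (see call_active_enhancers())")
  }
  n_e <- nrow(enhancers)
  agg_fun <- switch(aggregate, max = max, sum = sum, mean = mean)

  raw <- matrix(0, nrow = n_e, ncol = length(labels),
                dimnames = list(enhancers$enhancer_id, labels))
  for (f in seq_along(labels)) {
    pk <- factor_peaks[[f]]
    hits <- overlap_pairs(enhancers, pk, window_bp = 0)
    if (nrow(hits) > 0) {
      agg <- vapply(
        split(pk$signal_value[hits$idx_b], hits$idx_a),
        agg_fun, numeric(1)
      )
      raw[as.integer(names(agg)), f] <- agg
    }
  }
  structure(
    list(
      enhancer_ids = enhancers$enhancer_id,
      factors = labels,
      raw = raw,
      normalized = minmax_columns(raw)
    ),
    class = "signal_matrix"
  )
}

# per-column min-max scaling; constant columns (no dynamic range) map to 0
minmax_columns <- function(m) {
  out <- m
  for (j in seq_len(ncol(m))) {
    rng <- range(m[, j])
    out[, j] <- if (rng[1] == rng[2]) 0 else (m[, j] - rng[1]) / (rng[2] - rng[1])
  }
  out
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat(sprintf(
    "<signal_matrix> %d enhancers x %d factors (%.1f%% bound entries)\n",
    length(x$enhancer_ids), length(x$factors), 100 * mean(x$raw > 0)
  ))
  invisible(x)
}

#' Occupancy score per enhancer
#'
#' The occupancy score of an enhancer is the number of factors bound there
#' (raw signal > 0) multiplied by the sum of its min-max normalized factor
#' signals:
#' \deqn{OS(E) = N_E \times \sum_f Signal_E(f)}
#' Enhancers with no bound factor score 0.
#'
#' @param matrix A `signal_matrix` from [build_signal_matrix()].
#' @return A tibble with one row per enhancer: `enhancer_id`, `n_bound`,
#'   `os`, and `rank` (ascending in `os`).
#' @export
occupancy_score <- function(matrix) {
  stopifnot(inherits(matrix, "signal_matrix"))
  n_bound <- rowSums(matrix$raw > 0)
  os <- n_bound * rowSums(matrix$normalized)
  tibble(
    enhancer_id = matrix$enhancer_ids,
    n_bound = as.integer(n_bound),
    os = as.numeric(os),
    rank = rank(os, ties.method = "first")
  )
}

#' Inflection-point cutoff on a ranked signal curve
#'
#' Sorts the values ascending and scans the ranked curve from the low end for
#' the rank at which its discrete slope first exceeds the reference slope
#' `(max - min) / n` — the slope of a line spanning the whole ranked curve,
#' as in the ROSE super-enhancer method; the cutoff sits on the rank just
#' before that take-off point. Discrete slopes use a central difference over
#' `half_window` ranks. A curve that is at least as steep as its own chord
#' from the very first rank has no elbow, so the cutoff is the top value and
#' nothing lies above it. Values strictly above `cutoff_value` are "super".
#'
#' `mode = "local"` computes a second, lower cutoff for the sub-curve of
#' values at or below the global cutoff, re-using the global cutoff value as
#' the new maximum in the reference slope — the refinement used by the signal
#' predictor.
#'
#' @param values Numeric vector, length >= 3.
#' @param mode `"global"` (one pass) or `"local"` (second pass below the
#'   global cutoff).
#' @param half_window Half-width (in ranks) of the central difference used
#'   for discrete slopes.
#' @return A list with `cutoff_value`, `cutoff_rank` (index into the
#'   ascending-sorted curve the cutoff was taken from), `ref_slope`, `n`, and
#'   for local mode `global_cutoff`.
#' @export
find_inflection <- function(values, mode = c("global", "local"), half_window = 1) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(values), half_window >= 1)
  if (length(values) < 3) abort("find_inflection() needs at least 3 values")
  if (anyNA(values)) abort("find_inflection() does not accept NA values")

  res <- inflection_scan(sort(values), half_window)
  if (mode == "global") {
    return(res)
  }

  g <- res$cutoff_value
  lower <- sort(values[values <= g])
  if (length(lower) < 3) {
    # degenerate lower arm: fall back to the global cutoff
    return(c(res, list(global_cutoff = g)))
  }
  loc <- inflection_scan(lower, half_window, ref_max = g)
  c(loc, list(global_cutoff = g))
}

# Core scan on an ascending-sorted vector: walk up the ranked curve from the
# low end and stop where its discrete slope (central difference over
# half_window ranks) first exceeds the reference slope (max - min)/n; the
# cutoff sits on the last rank before that take-off. A curve whose very first
# slope already exceeds the reference has no elbow (it is uniformly at least
# as steep as its own chord), so the cutoff is the top value and nothing lies
# above it.
inflection_scan <- function(y, half_window, ref_max = NULL) {
  n <- length(y)
  ref_slope <- ((ref_max %||% y[n]) - y[1]) / n
  idx <- seq_len(n)
  lo <- pmax(idx - half_window, 1L)
  hi <- pmin(idx + half_window, n)
  slopes <- (y[hi] - y[lo]) / (hi - lo)
  above <- which(slopes > ref_slope)
  cutoff_rank <- if (length(above) == 0) {
    n
  } else if (above[1] == 1L) {
    n
  } else {
    above[1] - 1L
  }
  list(
    cutoff_value = y[cutoff_rank],
    cutoff_rank = cutoff_rank,
    ref_slope = ref_slope,
    n = n
  )
}

#' Classify enhancers into aSE / cSE / dSE / rEh
#'
#' Combines the occupancy-score cutoff with the classic (ROSE) super-enhancer
#' regions: enhancers with OS strictly above the inflection cutoff are
#' super-high-occupancy; those that also overlap a classic SE region are dual
#' super-enhancers (dSE) and those that do not are autonomous super-enhancers
#' (aSE). Below the cutoff, enhancers inside classic SE regions are
#' constituent super-enhancers (cSE) and the remainder are regular enhancers
#' (rEh). The four labels partition the active enhancer set.
#'
#' @param occ Occupancy tibble from [occupancy_score()], computed on exactly
#'   the enhancer set supplied here.
#' @param enhancers Active-enhancer tibble with `enhancer_id`.
#' @param classic_se A `classic_se_call` from [rose_classic_se()].
#' @param cutoff Optional pre-computed OS cutoff; by default
#'   [find_inflection()] (global mode) is applied to `occ$os`.
#' @return A tibble classed `enhancer_classes`: the enhancer columns plus
#'   `n_bound`, `os`, `rank`, `high_occupancy`, `in_classic_se` and `class`
#'   (factor with levels aSE, dSE, cSE, rEh). Attributes `cutoff_os` and
#'   `n_classic_se` record the inputs.
#' @export
classify_enhancers <- function(occ, enhancers, classic_se, cutoff = NULL) {
  stopifnot(inherits(classic_se, "classic_se_call"))
  if (nrow(occ) != nrow(enhancers) ||
      !identical(occ$enhancer_id, enhancers$enhancer_id)) {
    abort("occ and enhancers describe different enhancer sets")
  }
  cutoff_os <- cutoff %||% find_inflection(occ$os, mode = "global")$cutoff_value
  se_regions <- filter(classic_se$regions, .data$is_se)
  in_se <- overlaps_any(enhancers, se_regions, window_bp = 0)
  out <- as_tibble(enhancers)
  out <- mutate(
    out,
    n_bound = occ$n_bound,
    os = occ$os,
    rank = occ$rank,
    high_occupancy = occ$os > cutoff_os,
    in_classic_se = in_se,
    class = factor(
      case_when(
        high_occupancy & in_classic_se ~ "dSE",
        high_occupancy & !in_classic_se ~ "aSE",
        !high_occupancy & in_classic_se ~ "cSE",
        TRUE ~ "rEh"
      ),
      levels = c("aSE", "dSE", "cSE", "rEh")
    )
  )
  structure(
    out,
    cutoff_os = cutoff_os,
    n_classic_se = nrow(se_regions),
    class = c("enhancer_classes", class(tibble()))
  )
}

#' @export
print.enhancer_classes <- function(x, ...) {
  tab <- table(x$class)
  cat(sprintf(
    "<enhancer_classes> %d enhancers (OS cutoff %.4g): %s\n",
    nrow(x), attr(x, "cutoff_os"),
    paste(names(tab), tab, sep = " = ", collapse = ", ")
  ))
  NextMethod()
}
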