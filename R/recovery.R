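#' Compare pipeline classifications against planted truth
#'
#' Per-class precision and recall of the pipeline's aSE/dSE/cSE/rEh calls
#' against the generator's planted classes, plus a combined `high` row for
#' the aSE-or-dSE (super-high-occupancy) set — the primary recovery target.
#' Decoy and background records in the truth are excluded from the universe
#' (the pipeline is supposed to have removed them).
#'
#' @param truth Truth tibble from a `synthetic_bundle` (`enhancer_id`,
#'   `class`).
#' @param classes `enhancer_classes` tibble from [classify_enhancers()].
#' @return A tibble with rows aSE, dSE, cSE, rEh, high: `class`, `n_truth`,
#'   `n_called`, `precision`, `recall`. The planted-vs-called confusion
#'   matrix is attached as attribute `confusion`.
#' @export
recovery_report <- function(truth, classes) {
  planted <- filter(truth, .data$class %in% c("aSE", "dSE", "cSE", "rEh"))
  if (!setequal(planted$enhancer_id, classes$enhancer_id)) {
    abort(paste0(
      "enhancer universe mismatch between truth and classification (",
      length(setdiff(planted$enhancer_id, classes$enhancer_id)), " planted-only, ",
      length(setdiff(classes$enhancer_id, planted$enhancer_id)), " called-only)"
    ))
  }
  joined <- left_join(
    select(planted, "enhancer_id", planted_class = "class"),
    tibble(enhancer_id = classes$enhancer_id, called_class = as.character(classes$class)),
    by = "enhancer_id"
  )
  pr <- function(truth_set, called_set) {
    tp <- length(intersect(truth_set, called_set))
    tibble(
      n_truth = length(truth_set),
      n_called = length(called_set),
      precision = if (length(called_set)) tp / length(called_set) else NA_real_,
      recall = if (length(truth_set)) tp / length(truth_set) else NA_real_
    )
  }
  rows <- map(c("aSE", "dSE", "cSE", "rEh"), function(cl) {
    mutate(pr(
      joined$enhancer_id[joined$planted_class == cl],
      joined$enhancer_id[joined$called_class == cl]
    ), class = cl, .before = 1)
  })
  high <- mutate(pr(
    joined$enhancer_id[joined$planted_class %in% c("aSE", "dSE")],
    joined$enhancer_id[joined$called_class %in% c("aSE", "dSE")]
  ), class = "high", .before = 1)
  out <- bind_rows(c(rows, list(high)))
  attr(out, "confusion") <- table(
    planted = joined$planted_class,
    called = joined$called_class
  )
  out
}

#' Fraction of planted stitched runs recovered by a classic-SE call
#'
#' A planted run counts as recovered when its interval overlaps (>= 1 bp) at
#' least one called super-enhancer region.
#'
#' @param runs Run tibble from a `synthetic_bundle` (`chrom`, `start`, `end`).
#' @param classic_se A `classic_se_call`.
#' @return Fraction in `[0, 1]` (NA when no runs were planted).
#' @export
run_recovery <- function(runs, classic_se) {
  stopifnot(inherits(classic_se, "classic_se_call"))
  if (nrow(runs) == 0) return(NA_real_)
  se_regions <- filter(classic_se$regions, .data$is_se)
  mean(overlaps_any(runs, se_regions, window_bp = 0))
}
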