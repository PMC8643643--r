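#' Run the full enhancer-classification pipeline
#'
#' Convenience wrapper chaining the stages: active-enhancer calling (DNase
#' with H3K27ac support, TSS-excluded), enhancer-by-factor signal matrix,
#' occupancy scores with the inflection cutoff, the classic (ROSE)
#' super-enhancer call on H3K27ac, and the four-way aSE/dSE/cSE/rEh
#' classification.
#'
#' @param dnase,h3k27ac Peak tibbles.
#' @param tss TSS tibble.
#' @param factor_peaks Named list of TF/cofactor peak tibbles (histone marks
#'   should be left out).
#' @param tss_exclusion_bp Promoter exclusion half-width (default 2500).
#' @param stitch_distance ROSE stitching distance (default 12500).
#' @param aggregate Per-enhancer multi-peak aggregation for the signal
#'   matrix.
#' @return A list with `enhancers`, `matrix`, `occupancy`, `classic_se`,
#'   `classes` (see the individual stage functions).
#' @export
classify_enhancer_landscape <- function(dnase, h3k27ac, tss, factor_peaks,
                                        tss_exclusion_bp = 2500,
                                        stitch_distance = 12500,
                                        aggregate = "max") {
  enhancers <- call_active_enhancers(dnase, h3k27ac, tss,
                                     tss_exclusion_bp = tss_exclusion_bp)
  sm <- build_signal_matrix(enhancers, factor_peaks, aggregate = aggregate)
  occ <- occupancy_score(sm)
  se <- rose_classic_se(h3k27ac, stitch_distance = stitch_distance)
  classes <- classify_enhancers(occ, enhancers, se)
  list(
    enhancers = enhancers,
    matrix = sm,
    occupancy = occ,
    classic_se = se,
    classes = classes
  )
}
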