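#' Call active enhancers from DNase and H3K27ac peaks
#'
#' Two-step filter: keep DNase peaks that overlap at least one H3K27ac peak
#' (1 bp overlap, no window), then drop any that fall within +/- `tss_exclusion_bp`
#' of a transcription start site. The surviving DNase peaks are the active
#' enhancers used by every downstream stage.
#'
#' @param dnase,h3k27ac Peak tibbles ([read_narrowpeak()] layout; `chrom`,
#'   `start`, `end`, `signal_value` required).
#' @param tss TSS tibble ([read_tss()] layout: `gene_id`, `chrom`, `position`).
#' @param tss_exclusion_bp Half-width of the promoter-exclusion zone around
#'   each TSS (default 2500 bp).
#' @param tss_distance How the TSS distance is measured: `"edge"` (default)
#'   removes an enhancer when its interval shares any bp with the closed
#'   window `[tss - excl, tss + excl]`; `"center"` removes it when the peak
#'   midpoint lies within `excl` of the TSS.
#' @return A tibble of retained DNase peaks with an added `enhancer_id`
#'   column, classed `active_enhancer_set`, carrying a `provenance` attribute
#'   with the counts retained at each filter step (`n_dnase`,
#'   `n_h3k27ac_overlap`, `n_after_tss_exclusion`).
#' @export
call_active_enhancers <- function(dnase, h3k27ac, tss, tss_exclusion_bp = 2500,
                                  tss_distance = c("edge", "center")) {
  tss_distance <- match.arg(tss_distance)
  stopifnot(tss_exclusion_bp >= 0)
  dnase <- arrange(as_tibble(dnase), .data$chrom, .data$start, .data$end)

  prov <- list(n_dnase = nrow(dnase), n_h3k27ac_overlap = 0L, n_after_tss_exclusion = 0L)
  if (nrow(dnase) == 0) {
    out <- mutate(dnase, enhancer_id = character(0))
    return(new_enhancer_set(out, prov))
  }

  keep1 <- dnase[overlaps_any(dnase, h3k27ac, window_bp = 0), , drop = FALSE]
  prov$n_h3k27ac_overlap <- nrow(keep1)

  if (nrow(keep1) > 0 && nrow(tss) > 0) {
    if (tss_distance == "edge") {
      # closed window [tss - excl, tss + excl] as a half-open interval
      tss_win <- tibble(
        chrom = tss$chrom,
        start = pmax(tss$position - tss_exclusion_bp, 0),
        end = tss$position + tss_exclusion_bp + 1L
      )
      near_tss <- overlaps_any(keep1, tss_win, window_bp = 0)
    } else {
      mid <- tibble(
        chrom = keep1$chrom,
        start = as.integer((keep1$start + keep1$end) %/% 2),
        end = as.integer((keep1$start + keep1$end) %/% 2 + 1L)
      )
      tss_win <- tibble(
        chrom = tss$chrom,
        start = pmax(tss$position - tss_exclusion_bp, 0),
        end = tss$position + tss_exclusion_bp + 1L
      )
      near_tss <- overlaps_any(mid, tss_win, window_bp = 0)
    }
    keep2 <- keep1[!near_tss, , drop = FALSE]
  } else {
    keep2 <- keep1
  }
  prov$n_after_tss_exclusion <- nrow(keep2)

  keep2 <- mutate(
    keep2,
    enhancer_id = if ("name" %in% names(keep2) && !anyDuplicated(keep2$name)) {
      keep2$name
    } else {
      sprintf("enh_%05d", seq_len(nrow(keep2)))
    }
  )
  new_enhancer_set(keep2, prov)
}

new_enhancer_set <- function(df, provenance) {
  structure(
    df,
    provenance = provenance,
    class = c("active_enhancer_set", class(tibble()))
  )
}

#' @export
print.active_enhancer_set <- function(x, ...) {
  p <- attr(x, "provenance")
  cat(sprintf(
    "<active_enhancer_set> %d enhancers (DNase %d -> H3K27ac overlap %d -> TSS-filtered %d)\n",
    nrow(x), p$n_dnase, p$n_h3k27ac_overlap, p$n_after_tss_exclusion
  ))
  NextMethod()
}

#' Stitch peaks within a fixed distance into regions
#'
#' Consecutive peaks on one chromosome merge into a single region when the
#' gap between them (next start minus previous end) is at most
#' `stitch_distance`; merging is transitive. This is the ROSE stitching step
#' with its 12.5 kb default.
#'
#' @param peaks Peak tibble with `chrom`, `start`, `end`, `signal_value`.
#' @param stitch_distance Maximum gap (bp) bridged by stitching.
#' @return A tibble of regions: `chrom`, `start`, `end`, `n_peaks`,
#'   `total_signal` (sum of member signal values) and `member_idx` (list
#'   column of row indices into `peaks`), sorted by coordinate.
#' @export
stitch_peaks <- function(peaks, stitch_distance = 12500) {
  stopifnot(stitch_distance >= 0)
  peaks <- as_tibble(peaks)
  if (nrow(peaks) == 0) {
    return(tibble(
      chrom = character(), start = integer(), end = integer(),
      n_peaks = integer(), total_signal = numeric(), member_idx = list()
    ))
  }
  gr <- peaks_to_granges(peaks)
  red <- GenomicRanges::reduce(gr, min.gapwidth = stitch_distance + 1, with.revmap = TRUE)
  members <- as.list(S4Vectors::mcols(red)$revmap)
  out <- tibble(
    chrom = as.character(GenomicRanges::seqnames(red)),
    start = GenomicRanges::start(red) - 1L,
    end = GenomicRanges::end(red),
    n_peaks = lengths(members),
    total_signal = map_dbl(members, function(i) sum(peaks$signal_value[i])),
    member_idx = map(members, as.integer)
  )
  arrange(out, .data$chrom, .data$start)
}

#' ROSE-style classic super-enhancer call
#'
#' Stitches H3K27ac peaks (12.5 kb default, no TSS exclusion inside the
#' stitching step), ranks the stitched regions by total signal and places the
#' cutoff at the ranked curve's inflection point ([find_inflection()], global
#' mode). Regions with total signal strictly above the cutoff are the classic
#' super-enhancers.
#'
#' @param h3k27ac H3K27ac peak tibble.
#' @param stitch_distance Stitching distance in bp (default 12500).
#' @return An object of class `classic_se_call`: list with `regions` (the
#'   stitched-region tibble plus `rank` ascending in total signal and `is_se`),
#'   `cutoff_signal` and `stitch_distance`.
#' @export
rose_classic_se <- function(h3k27ac, stitch_distance = 12500) {
  regions <- stitch_peaks(h3k27ac, stitch_distance)
  if (nrow(regions) < 2) {
    if (nrow(regions) > 0) {
      warn("fewer than 2 stitched regions; no super-enhancer call possible")
    }
    regions <- mutate(regions,
      rank = rank(.data$total_signal, ties.method = "first"),
      is_se = FALSE
    )
    out <- list(
      regions = regions,
      cutoff_signal = if (nrow(regions)) max(regions$total_signal) else NA_real_,
      stitch_distance = stitch_distance
    )
    return(structure(out, class = "classic_se_call"))
  }
  infl <- find_inflection(regions$total_signal, mode = "global")
  regions <- mutate(
    regions,
    rank = rank(.data$total_signal, ties.method = "first"),
    is_se = .data$total_signal > infl$cutoff_value
  )
  structure(
    list(
      regions = regions,
      cutoff_signal = infl$cutoff_value,
      stitch_distance = stitch_distance
    ),
    class = "classic_se_call"
  )
}

#' @export
print.classic_se_call <- function(x, ...) {
  cat(sprintf(
    "<classic_se_call> %d stitched regions, %d super-enhancers (signal cutoff %.4g, stitch %d bp)\n",
    nrow(x$regions), sum(x$regions$is_se), x$cutoff_signal, x$stitch_distance
  ))
  invisible(x)
}
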