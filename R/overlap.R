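#' Find overlapping interval pairs between two peak tables
#'
#' The workhorse overlap engine: reports every pair (i, j) such that interval
#' i of `a`, expanded by `window_bp` on both sides (start clamped at 0),
#' shares at least one base with interval j of `b` on the same chromosome.
#' `window_bp = 0` is plain intersection; `window_bp = 1000` reproduces
#' `bedtools window` at its default 1 kb gap, the setting used to intersect
#' loop arms with enhancers and TSSs.
#'
#' @param a,b Data frames with `chrom`, `start`, `end` columns (0-based
#'   half-open).
#' @param window_bp Non-negative expansion in bp applied to `a`.
#' @return A tibble with integer columns `idx_a`, `idx_b` (row indices into
#'   `a` and `b`), sorted by (`idx_a`, `idx_b`); each qualifying pair appears
#'   exactly once.
#'
#' @examples
#' a <- tibble::tibble(chrom = "chr1", start = 100L, end = 200L)
#' b <- tibble::tibble(chrom = "chr1", start = 900L, end = 1000L)
#' overlap_pairs(a, b, window_bp = 0)     # empty
#' overlap_pairs(a, b, window_bp = 1000)  # one pair
#' @export
overlap_pairs <- function(a, b, window_bp = 0) {
  stopifnot(is.data.frame(a), is.data.frame(b), length(window_bp) == 1,
            is.finite(window_bp), window_bp >= 0)
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(tibble(idx_a = integer(), idx_b = integer()))
  }
  gr_a <- peaks_to_granges(a, expand = window_bp)
  gr_b <- peaks_to_granges(b)
  # disjoint chromosome name spaces are a legitimate no-pair case, not a
  # condition worth a seqlevel warning
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(gr_a, gr_b, minoverlap = 1L)
  )
  out <- tibble(
    idx_a = S4Vectors::queryHits(hits),
    idx_b = S4Vectors::subjectHits(hits)
  )
  arrange(out, .data$idx_a, .data$idx_b)
}

# 0-based half-open tibble -> GRanges (1-based closed), optionally expanded.
# Expansion clamps the start at genome position 0; no right clamp (chromosome
# lengths are not required).
peaks_to_granges <- function(x, expand = 0) {
  start0 <- pmax(x$start - expand, 0)
  end0 <- x$end + expand
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = start0 + 1, end = end0)
  )
}

# convenience: which rows of `a` hit >= 1 row of `b`
overlaps_any <- function(a, b, window_bp = 0) {
  hits <- overlap_pairs(a, b, window_bp)
  seq_len(nrow(a)) %in% hits$idx_a
}
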