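#' GC and CpG composition of genomic intervals
#'
#' For each interval, computes the GC percentage (100 * (#G + #C) / width) and
#' the CpG percentage (100 * #CG dinucleotides / (width - 1)). Counting is
#' case-insensitive; ambiguous bases (N etc.) count as non-GC and interrupt
#' CpG dinucleotides.
#'
#' @param seqs Named character vector (or `DNAStringSet`) of chromosome
#'   sequences, names matching `intervals$chrom`.
#' @param intervals Data frame with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @return `intervals` with added columns `gc_percent` and `cpg_percent`.
#' @export
sequence_composition <- function(seqs, intervals) {
  if (methods::is(seqs, "DNAStringSet")) {
    seqs <- as.character(seqs)
  }
  stopifnot(is.character(seqs), !is.null(names(seqs)), is.data.frame(intervals))
  missing_chrom <- setdiff(unique(intervals$chrom), names(seqs))
  if (length(missing_chrom) > 0) {
    abort(paste0("no sequence for chrom: ", paste(missing_chrom, collapse = ", ")))
  }
  lens <- nchar(seqs)[intervals$chrom]
  beyond <- which(intervals$end > lens | intervals$start < 0)
  if (length(beyond) > 0) {
    i <- beyond[1]
    abort(sprintf(
      "interval %s:%d-%d extends beyond the %d bp sequence",
      intervals$chrom[i], intervals$start[i], intervals$end[i], lens[i]
    ))
  }
  sub <- toupper(substr(seqs[intervals$chrom], intervals$start + 1, intervals$end))
  ss <- Biostrings::DNAStringSet(sub)
  width <- intervals$end - intervals$start
  gc <- rowSums(Biostrings::letterFrequency(ss, c("G", "C")))
  cg <- Biostrings::vcountPattern("CG", ss)
  mutate(
    as_tibble(intervals),
    gc_percent = 100 * gc / width,
    cpg_percent = ifelse(width > 1, 100 * cg / (width - 1), 0)
  )
}
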