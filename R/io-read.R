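#' Read an ENCODE narrowPeak (or plain BED) file into a peak tibble
#'
#' narrowPeak is BED6+4: chrom, start, end, name, score, strand, signalValue,
#' pValue, qValue, summit offset (peak column; -1 when no summit was called).
#' Plain BED3/BED4/BED6 files are also accepted; the signal column can then be
#' designated with `signal_col`, and when no signal column exists every peak
#' receives `signal_value = 1` (with a warning).
#'
#' @param path Path to a tab-separated narrowPeak/BED file (no header).
#' @param signal_col For non-narrowPeak input, 1-based column index holding
#'   the signal value. Ignored for 10-column narrowPeak input (column 7 is
#'   used, per the format definition).
#' @param label Optional assay/factor label stored in the `label` column.
#'
#' @return A tibble sorted by (`chrom`, `start`) with columns `chrom`,
#'   `start`, `end` (0-based half-open), `name`, `score`, `strand`,
#'   `signal_value`, `p_value`, `q_value`, `summit_offset`, `label`.
#'
#' @examples
#' p <- tempfile(fileext = ".narrowPeak")
#' writeLines("chr1\t100\t600\tpk1\t0\t.\t8.5\t-1\t-1\t250", p)
#' read_narrowpeak(p)
#' @export
read_narrowpeak <- function(path, signal_col = NULL, label = NA_character_) {
  raw <- readr::read_tsv(
    path,
    col_names = FALSE,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (nrow(raw) == 0) {
    return(empty_peakset(label))
  }
  ncol_in <- ncol(raw)
  if (ncol_in < 3) {
    abort(sprintf("'%s' has %d column(s); need at least chrom/start/end", path, ncol_in))
  }

  start <- parse_coord(raw[[2]], path, "start")
  end <- parse_coord(raw[[3]], path, "end")
  bad <- which(start >= end)
  if (length(bad) > 0) {
    abort(sprintf("'%s' line %d: start (%d) >= end (%d)", path, bad[1], start[bad[1]], end[bad[1]]))
  }
  if (any(start < 0)) {
    abort(sprintf("'%s' line %d: negative start", path, which(start < 0)[1]))
  }

  if (ncol_in >= 10) {
    sig <- suppressWarnings(as.numeric(raw[[7]]))
  } else if (!is.null(signal_col)) {
    if (signal_col > ncol_in) {
      abort(sprintf("signal_col = %d but '%s' has only %d columns", signal_col, path, ncol_in))
    }
    sig <- suppressWarnings(as.numeric(raw[[signal_col]]))
  } else {
    warn(sprintf("'%s' has no signal column; using signal_value = 1 for all peaks", path))
    sig <- rep(1, nrow(raw))
  }
  if (anyNA(sig)) {
    abort(sprintf("'%s' line %d: non-numeric signal value", path, which(is.na(sig))[1]))
  }
  if (any(sig < 0)) {
    abort(sprintf("'%s' line %d: negative signal value", path, which(sig < 0)[1]))
  }

  out <- tibble(
    chrom = raw[[1]],
    start = start,
    end = end,
    name = if (ncol_in >= 4) raw[[4]] else paste0("peak_", seq_len(nrow(raw))),
    score = if (ncol_in >= 5) suppressWarnings(as.numeric(raw[[5]])) else 0,
    strand = if (ncol_in >= 6) raw[[6]] else ".",
    signal_value = sig,
    p_value = if (ncol_in >= 10) suppressWarnings(as.numeric(raw[[8]])) else -1,
    q_value = if (ncol_in >= 10) suppressWarnings(as.numeric(raw[[9]])) else -1,
    summit_offset = if (ncol_in >= 10) as.integer(raw[[10]]) else -1L,
    label = label
  )
  arrange(out, .data$chrom, .data$start, .data$end)
}

parse_coord <- function(x, path, what) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) | v != floor(v))
  if (length(bad) > 0) {
    abort(sprintf("'%s' line %d: non-integer %s '%s'", path, bad[1], what, x[bad[1]]))
  }
  as.integer(v)
}

empty_peakset <- function(label = NA_character_) {
  tibble(
    chrom = character(), start = integer(), end = integer(),
    name = character(), score = numeric(), strand = character(),
    signal_value = numeric(), p_value = numeric(), q_value = numeric(),
    summit_offset = integer(), label = character()
  )
}

#' Write a peak tibble back to narrowPeak
#'
#' Writes the canonical 10 columns; reading the result with
#' [read_narrowpeak()] reproduces the coordinate, name and signal fields
#' exactly.
#'
#' @param peaks Peak tibble as produced by [read_narrowpeak()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  stopifnot(is.data.frame(peaks))
  df <- tibble(
    chrom = peaks$chrom,
    start = peaks$start,
    end = peaks$end,
    name = peaks$name %||% paste0("peak_", seq_len(nrow(peaks))),
    score = peaks$score %||% 0,
    strand = peaks$strand %||% ".",
    signal_value = peaks$signal_value %||% 1,
    p_value = peaks$p_value %||% -1,
    q_value = peaks$q_value %||% -1,
    summit_offset = peaks$summit_offset %||% -1L
  )
  readr::write_tsv(df, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a TSS table
#'
#' Expects a tab-separated file with a header line and columns `gene_id`,
#' `chrom`, `position` (0-based point coordinate of the transcription start
#' site) and `strand`.
#'
#' @param path Path to the TSV file.
#' @return A tibble with those four columns, sorted by (`chrom`, `position`).
#' @export
read_tss <- function(path) {
  out <- readr::read_tsv(
    path,
    col_types = readr::cols(
      gene_id = readr::col_character(),
      chrom = readr::col_character(),
      position = readr::col_integer(),
      strand = readr::col_character()
    ),
    progress = FALSE
  )
  if (any(out$position < 0)) abort("TSS positions must be >= 0")
  if (anyDuplicated(out$gene_id)) abort("duplicate gene_id in TSS table")
  arrange(out, .data$chrom, .data$position)
}

#' Read a BEDPE loop file
#'
#' Expects at least 6 columns (chrom1, start1, end1, chrom2, start2, end2);
#' column 7 is the loop name and column 8 the contact (PET) count. Missing
#' name/contact columns get defaults of `loop_<i>` / 1.
#'
#' @param path Path to the BEDPE file (no header).
#' @param contacts_col 1-based index of the contact-count column (default 8,
#'   the BEDPE score slot).
#' @return A tibble with columns `loop_id`, `chrom1`, `start1`, `end1`,
#'   `chrom2`, `start2`, `end2`, `contacts`.
#' @export
read_bedpe <- function(path, contacts_col = 8) {
  raw <- readr::read_tsv(
    path,
    col_names = FALSE,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (nrow(raw) == 0) {
    return(tibble(
      loop_id = character(), chrom1 = character(), start1 = integer(),
      end1 = integer(), chrom2 = character(), start2 = integer(),
      end2 = integer(), contacts = integer()
    ))
  }
  if (ncol(raw) < 6) abort(sprintf("'%s' has fewer than 6 BEDPE columns", path))
  contacts <- if (ncol(raw) >= contacts_col) {
    as.integer(round(suppressWarnings(as.numeric(raw[[contacts_col]]))))
  } else {
    rep(1L, nrow(raw))
  }
  contacts[is.na(contacts)] <- 1L
  if (any(contacts < 1)) abort("loop contact counts must be >= 1")
  tibble(
    loop_id = if (ncol(raw) >= 7) raw[[7]] else paste0("loop_", seq_len(nrow(raw))),
    chrom1 = raw[[1]],
    start1 = parse_coord(raw[[2]], path, "start1"),
    end1 = parse_coord(raw[[3]], path, "end1"),
    chrom2 = raw[[4]],
    start2 = parse_coord(raw[[5]], path, "start2"),
    end2 = parse_coord(raw[[6]], path, "end2"),
    contacts = contacts
  )
}

#' Read a gene-expression table (gene_id, fpkm)
#'
#' @param path Path to a TSV with header columns `gene_id` and `fpkm`.
#' @return A tibble with columns `gene_id`, `fpkm`.
#' @export
read_expression <- function(path) {
  readr::read_tsv(
    path,
    col_types = readr::cols(
      gene_id = readr::col_character(),
      fpkm = readr::col_double()
    ),
    progress = FALSE
  )
}

#' Read an annotated footprint BED file
#'
#' BED6+3 with extra columns `motif_id`, `dbd_family`, `bitscore`; one row per
#' motif match. Rows sharing coordinates belong to one physical footprint and
#' receive the same `footprint_id`.
#'
#' @param path Path to the footprint BED file (no header).
#' @return A tibble with one row per motif match: `footprint_id`, `chrom`,
#'   `start`, `end`, `motif_id`, `dbd_family`, `bitscore`.
#' @export
read_footprints <- function(path) {
  raw <- readr::read_tsv(
    path,
    col_names = FALSE,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (nrow(raw) == 0) {
    return(tibble(
      footprint_id = character(), chrom = character(), start = integer(),
      end = integer(), motif_id = character(), dbd_family = character(),
      bitscore = numeric()
    ))
  }
  if (ncol(raw) < 9) abort(sprintf("'%s': footprint BED needs 9 columns (BED6 + motif_id, dbd_family, bitscore)", path))
  out <- tibble(
    chrom = raw[[1]],
    start = parse_coord(raw[[2]], path, "start"),
    end = parse_coord(raw[[3]], path, "end"),
    motif_id = raw[[7]],
    dbd_family = raw[[8]],
    bitscore = suppressWarnings(as.numeric(raw[[9]]))
  )
  if (anyNA(out$bitscore) || any(!is.finite(out$bitscore))) {
    abort(sprintf("'%s': non-finite bitscore", path))
  }
  out <- arrange(out, .data$chrom, .data$start, .data$end)
  key <- paste(out$chrom, out$start, out$end)
  out$footprint_id <- paste0("fp_", match(key, unique(key)))
  select(out, "footprint_id", "chrom", "start", "end", "motif_id", "dbd_family", "bitscore")
}

#' Read a FASTA file into a named character vector of sequences
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] returning plain
#' uppercase character strings named by record id, the form
#' [sequence_composition()] consumes.
#'
#' @param path Path to an (uncompressed) FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}
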