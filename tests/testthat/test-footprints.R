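fp_tbl <- function(chrom, start, end, family = "NR", bitscore = 10,
                   motif = NULL) {
  tibble::tibble(
    footprint_id = paste0("fp", seq_along(start)),
    chrom = chrom, start = as.integer(start), end = as.integer(end),
    motif_id = motif %||% paste0("m", seq_along(start)),
    dbd_family = family, bitscore = bitscore
  )
}

test_that("consensus filtering keeps only overlapping footprints", {
  fp <- fp_tbl("chr1", c(100, 300), c(115, 320))
  cons <- tibble::tibble(chrom = "chr1", start = c(110L, 320L), end = c(130L, 340L))
  kept <- filter_consensus(fp, cons)
  # [100,115) overlaps [110,130); [300,320) is merely adjacent to [320,340)
  expect_equal(kept$start, 100L)

  withr::local_seed(13)
  for (trial in 1:10) {
    fp_r <- rand_peaks(40)
    fp_r <- tibble::tibble(
      footprint_id = paste0("fp", seq_len(nrow(fp_r))),
      chrom = fp_r$chrom, start = fp_r$start, end = fp_r$end,
      motif_id = "m", dbd_family = "NR", bitscore = 10
    )
    cons_r <- rand_peaks(25)
    kept_r <- filter_consensus(fp_r, cons_r)
    exp_keep <- unique(oracle_overlap(fp_r, cons_r, 0)$idx_a)
    expect_setequal(kept_r$footprint_id, fp_r$footprint_id[exp_keep])
  }
})

test_that("footprint statistics compute widths and floored gaps per enhancer", {
  enh <- tibble::tibble(chrom = "chr1", start = 0L, end = 1000L, enhancer_id = "e1")
  fp <- fp_tbl("chr1", c(100, 120), c(110, 135))
  st <- footprint_stats(enh, fp)
  expect_equal(st$n_footprints, 2L)
  expect_equal(st$widths[[1]], c(10, 15))
  expect_equal(st$gaps[[1]], 10)

  # overlapping footprints yield gap 0
  fp2 <- fp_tbl("chr1", c(100, 115), c(120, 130))
  expect_equal(footprint_stats(enh, fp2)$gaps[[1]], 0)

  # a footprint straddling two enhancers counts fully in both
  enh2 <- tibble::tibble(chrom = "chr1", start = c(0L, 490L),
                         end = c(500L, 900L), enhancer_id = c("e1", "e2"))
  fp3 <- fp_tbl("chr1", 485, 505)
  st3 <- footprint_stats(enh2, fp3)
  expect_equal(st3$n_footprints, c(1L, 1L))
  expect_equal(st3$widths[[1]], 20)
  expect_equal(st3$widths[[2]], 20)
})

test_that("gap count equals footprint count minus one on synthetic data", {
  b <- get_small_bundle()
  enh <- dplyr::mutate(dplyr::filter(b$truth, class %in% c("aSE", "dSE", "cSE", "rEh")))
  st <- footprint_stats(enh, b$footprints)
  with_fp <- st[st$n_footprints >= 1, ]
  expect_equal(lengths(with_fp$gaps), with_fp$n_footprints - 1L)
  expect_equal(lengths(st$widths), st$n_footprints)
})

test_that("DBD assignment takes the best bitscore with deterministic tie-break", {
  fp <- tibble::tibble(
    footprint_id = c("f1", "f1", "f2", "f3", "f3"),
    chrom = "chr1", start = c(10L, 10L, 50L, 90L, 90L), end = c(25L, 25L, 60L, 99L, 99L),
    motif_id = c("m1", "m2", "m3", "m4", "m5"),
    dbd_family = c("NR", "C2H2", "bZIP", "HMG", "bHLH"),
    bitscore = c(12.3, 15.1, 9, 11, 11)
  )
  asg <- assign_dbd(fp)
  expect_equal(asg$dbd_family[asg$footprint_id == "f1"], "C2H2")
  expect_equal(asg$dbd_family[asg$footprint_id == "f3"], "HMG")  # tie -> lexicographic

  # deterministic across row orderings
  asg2 <- assign_dbd(fp[sample(nrow(fp)), ])
  expect_equal(dplyr::arrange(asg, footprint_id), dplyr::arrange(asg2, footprint_id))
})

test_that("binding mode distinguishes direct, indirect and unbound", {
  enh <- tibble::tibble(chrom = "chr1", start = c(0L, 1000L, 2000L),
                        end = c(500L, 1500L, 2500L),
                        enhancer_id = c("e1", "e2", "e3"))
  fp <- dplyr::bind_rows(
    fp_tbl("chr1", 100, 120, family = "NR"),
    fp_tbl("chr1", 1100, 1120, family = "bZIP")
  )
  st <- footprint_stats(enh, fp)
  tf_peaks <- peaks_tbl("chr1", c(50, 1050), c(200, 1200))
  ann <- annotate_binding(tf_peaks, "TF1", "NR", enh, st)
  expect_equal(ann$mode, c("direct", "indirect", "unbound"))

  expect_warning(
    ann_na <- annotate_binding(tf_peaks, "TF2", NA, enh, st),
    "no DBD family"
  )
  expect_equal(ann_na$mode, c("indirect", "indirect", "unbound"))
})

test_that("anchoring calls require both strict 50% thresholds", {
  mk_ann <- function(n_bound, n_direct, n = 100) {
    tibble::tibble(
      tf = "TF",
      enhancer_id = sprintf("e%03d", 1:n),
      bound = c(rep(TRUE, n_bound), rep(FALSE, n - n_bound)),
      mode = c(rep("direct", n_direct), rep("indirect", n_bound - n_direct),
               rep("unbound", n - n_bound))
    )
  }
  classes <- tibble::tibble(enhancer_id = sprintf("e%03d", 1:100), class = "aSE")

  res <- suppressWarnings(call_anchoring_tfs(mk_ann(96, 80), classes))
  expect_equal(res$pct_peaks_bound, 96)
  expect_equal(res$pct_bound_with_motif, 100 * 80 / 96, tolerance = 1e-12)
  expect_true(res$is_anchor)

  # fully bound but never direct: not an anchor
  expect_false(suppressWarnings(call_anchoring_tfs(mk_ann(100, 0), classes))$is_anchor)
  # exactly 50% bound: strict threshold, not an anchor
  expect_false(suppressWarnings(call_anchoring_tfs(mk_ann(50, 50), classes))$is_anchor)
  # empty classes produce a warning
  expect_warning(call_anchoring_tfs(mk_ann(96, 80), classes), "empty")
})

test_that("binding modes partition each class and aSE footprints outnumber rEh", {
  b <- get_small_bundle()
  res <- get_small_pipeline()
  enh <- res$enhancers
  st <- footprint_stats(enh, filter_consensus(b$footprints, b$consensus))
  ann <- annotate_binding(b$factors[[1]], names(b$factors)[1], "NR", enh, st)
  counts <- table(ann$mode)
  expect_equal(sum(counts), nrow(enh))

  truth_class <- b$truth$class[match(enh$enhancer_id, b$truth$enhancer_id)]
  n_ase <- st$n_footprints[truth_class == "aSE"]
  n_reh <- st$n_footprints[truth_class == "rEh"]
  w_ase <- unlist(st$widths[truth_class == "aSE"])
  w_reh <- unlist(st$widths[truth_class == "rEh"])
  expect_gt(mean(n_ase), mean(n_reh))
  expect_gt(mean(w_ase), mean(w_reh))
})
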