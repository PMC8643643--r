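make_enh <- function(n, width = 500, gap = 10000) {
  start <- seq(0, by = width + gap, length.out = n)
  tibble::tibble(
    chrom = "chr1", start = as.integer(start), end = as.integer(start + width),
    enhancer_id = sprintf("e%02d", seq_len(n))
  )
}

test_that("signal matrix aggregates multi-peak factors and normalizes per column", {
  enh <- make_enh(3)
  # factor A: two peaks on enhancer 1 (signals 3 and 7), one on enhancer 2
  fa <- peaks_tbl("chr1", c(0, 250, 10500), c(200, 450, 10900), signal = c(3, 7, 5))
  # factor B: signals 0-range col: only enhancer 3
  fb <- peaks_tbl("chr1", 21000, 21400, signal = 4)
  sm <- build_signal_matrix(enh, list(A = fa, B = fb))
  expect_equal(unname(sm$raw[, "A"]), c(7, 5, 0))   # max aggregation
  expect_equal(unname(sm$raw[, "B"]), c(0, 0, 4))
  expect_equal(unname(sm$normalized[, "A"]), c(1, 5 / 7, 0))

  sm_sum <- build_signal_matrix(enh, list(A = fa), aggregate = "sum")
  expect_equal(unname(sm_sum$raw[, "A"]), c(10, 5, 0))
  sm_mean <- build_signal_matrix(enh, list(A = fa), aggregate = "mean")
  expect_equal(unname(sm_mean$raw[, "A"]), c(5, 5, 0))

  expect_error(build_signal_matrix(enh, list(A = fa, fb)), "named")
  expect_error(
    build_signal_matrix(enh, stats::setNames(list(fa, fb), c("A", "A"))),
    "unique"
  )
})

test_that("min-max columns hit the unit interval endpoints; constant columns zero out", {
  m <- matrix(c(0, 5, 10, 3, 3, 3), ncol = 2)
  norm <- asescope:::minmax_columns(m)
  expect_equal(norm[, 1], c(0, 0.5, 1))
  expect_equal(norm[, 2], c(0, 0, 0))
})

test_that("occupancy score implements OS = N x sum(normalized)", {
  enh <- make_enh(2)
  fa <- peaks_tbl("chr1", c(0, 10500), c(400, 10900), signal = c(8, 2))
  fb <- peaks_tbl("chr1", c(0, 10500), c(400, 10900), signal = c(4, 1))
  fc <- peaks_tbl("chr1", c(0, 10500), c(400, 10900), signal = c(5, 5))
  sm <- build_signal_matrix(enh, list(A = fa, B = fb, C = fc))
  occ <- occupancy_score(sm)
  # normalized rows: (1, 1, 0) and (0, 0, 0) -- the constant column C zeroes
  # out after normalization but still counts towards N
  expect_equal(occ$n_bound, c(3L, 3L))
  expect_equal(occ$os[1], 3 * 2)
  expect_equal(occ$os[2], 3 * 0)
})

test_that("occupancy score matches the per-row oracle on random matrices", {
  withr::local_seed(21)
  for (trial in 1:10) {
    raw <- matrix(rlnorm(500) * rbinom(500, 1, 0.6), nrow = 50)
    sm <- structure(
      list(enhancer_ids = sprintf("e%02d", 1:50),
           factors = sprintf("f%02d", 1:10),
           raw = raw, normalized = asescope:::minmax_columns(raw)),
      class = "signal_matrix"
    )
    occ <- occupancy_score(sm)
    expect_equal(occ$os, oracle_os(raw, sm$normalized))

    # invariance to factor column order
    perm <- sample(10)
    sm_p <- sm
    sm_p$raw <- raw[, perm]
    sm_p$normalized <- sm$normalized[, perm]
    sm_p$factors <- sm$factors[perm]
    expect_equal(occupancy_score(sm_p)$os, occ$os)

    # an all-zero factor column changes nothing
    sm_z <- sm
    sm_z$raw <- cbind(raw, 0)
    sm_z$normalized <- cbind(sm$normalized, 0)
    sm_z$factors <- c(sm$factors, "fz")
    expect_equal(occupancy_score(sm_z)$os, occ$os)
  }
})

test_that("inflection cutoff lands at the hockey-stick junction", {
  y <- c(rep(0, 90), seq(10, 100, by = 10))
  res <- find_inflection(y)
  expect_equal(res$cutoff_value, 0)
  expect_equal(sum(y > res$cutoff_value), 10)  # the whole ramp is super
  expect_equal(res$ref_slope, 1)

  # flat curve: cutoff at the constant, nothing above
  flat <- find_inflection(rep(5, 10))
  expect_equal(flat$cutoff_value, 5)
  expect_equal(sum(rep(5, 10) > flat$cutoff_value), 0)

  # strictly linear curve: no elbow, zero values strictly above the cutoff
  lin <- find_inflection(as.numeric(1:50))
  expect_equal(sum(1:50 > lin$cutoff_value), 0)

  expect_error(find_inflection(c(1, 2)), "at least 3")
})

test_that("inflection cutoff matches the literal scan oracle on random curves", {
  withr::local_seed(31)
  for (trial in 1:40) {
    y <- switch(1 + trial %% 3,
      rlnorm(80, 0, 1),
      c(rep(0, 50), sort(rlnorm(30, 2, 0.5))),
      runif(60) * trial
    )
    hw <- sample(1:3, 1)
    got <- find_inflection(y, half_window = hw)
    exp <- oracle_inflection(y, half_window = hw)
    expect_equal(got$cutoff_rank, exp$cutoff_rank)
    expect_equal(got$cutoff_value, exp$cutoff_value)
  }
})

test_that("inflection cutoff is equivariant under positive affine transforms", {
  withr::local_seed(17)
  for (trial in 1:20) {
    y <- c(rep(0, 40), sort(rlnorm(20, 1, 0.8)))
    a <- runif(1, 0.5, 20)
    b <- runif(1, -5, 5)
    res <- find_inflection(y)
    res_t <- find_inflection(a * y + b)
    expect_equal(res_t$cutoff_rank, res$cutoff_rank)
    expect_equal(res_t$cutoff_value, a * res$cutoff_value + b, tolerance = 1e-12)
  }
})

test_that("four-way classification follows occupancy and classic-SE overlap", {
  enh <- make_enh(4)
  # classic SE region covering enhancers 2 and 4
  se_regions <- tibble::tibble(
    chrom = "chr1", start = c(10200L, 31200L), end = c(10800L, 31800L),
    n_peaks = 1L, total_signal = 50, member_idx = list(1L, 2L),
    rank = 1:2, is_se = TRUE
  )
  classic <- structure(
    list(regions = se_regions, cutoff_signal = 10, stitch_distance = 12500),
    class = "classic_se_call"
  )
  occ <- tibble::tibble(
    enhancer_id = enh$enhancer_id,
    n_bound = c(5L, 6L, 1L, 0L),
    os = c(9, 8, 1, 0.5),
    rank = c(4L, 3L, 2L, 1L)
  )
  cls <- classify_enhancers(occ, enh, classic, cutoff = 2)
  expect_equal(as.character(cls$class), c("aSE", "dSE", "rEh", "cSE"))
  expect_equal(attr(cls, "cutoff_os"), 2)

  expect_error(classify_enhancers(occ[1:3, ], enh, classic), "different")
})

test_that("classification labels partition every synthetic run", {
  res <- get_small_pipeline()
  cls <- res$classes
  expect_equal(nrow(cls), nrow(res$enhancers))
  expect_false(anyNA(cls$class))
  # the four (high_occupancy, in_classic_se) combinations map 1:1 to labels
  expect_true(all((cls$class == "dSE") == (cls$high_occupancy & cls$in_classic_se)))
  expect_true(all((cls$class == "aSE") == (cls$high_occupancy & !cls$in_classic_se)))
  expect_true(all((cls$class == "cSE") == (!cls$high_occupancy & cls$in_classic_se)))
  expect_true(all((cls$class == "rEh") == (!cls$high_occupancy & !cls$in_classic_se)))
  expect_true(all(cls$high_occupancy == (cls$os > attr(cls, "cutoff_os"))))
})
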