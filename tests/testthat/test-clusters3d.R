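mk_loop <- function(chrom1, s1, chrom2, s2, contacts = 1, width = 1000) {
  tibble::tibble(
    loop_id = paste0("L", seq_along(s1)),
    chrom1 = chrom1, start1 = as.integer(s1), end1 = as.integer(s1 + width),
    chrom2 = chrom2, start2 = as.integer(s2), end2 = as.integer(s2 + width),
    contacts = as.integer(contacts)
  )
}

# hand-annotated loops: build the annotate output directly
annotate_manual <- function(loops, left_e, right_e, left_g = NULL, right_g = NULL) {
  empty <- rep(list(character(0)), nrow(loops))
  dplyr::mutate(loops,
    left_enhancers = left_e, right_enhancers = right_e,
    left_genes = left_g %||% empty, right_genes = right_g %||% empty
  )
}

test_that("loop arms match enhancers within the 1 kb window but not beyond", {
  loops <- mk_loop("chr1", 5000, "chr1", 50000)
  enh <- tibble::tibble(chrom = "chr1", start = 6500L, end = 6800L, enhancer_id = "E1")
  tss <- tibble::tibble(gene_id = "g1", chrom = "chr1", position = 51500L, strand = "+")

  ann <- annotate_loop_arms(loops, enh, tss, window_bp = 1000)
  expect_equal(ann$left_enhancers[[1]], "E1")   # gap 500 <= 1 kb
  expect_equal(ann$right_genes[[1]], "g1")      # TSS 500 beyond the arm end

  ann0 <- annotate_loop_arms(loops, enh, tss, window_bp = 0)
  expect_equal(ann0$left_enhancers[[1]], character(0))
  expect_equal(ann0$right_genes[[1]], character(0))
})

test_that("loops sharing an enhancer merge into one cluster with unique counts", {
  loops <- mk_loop("chr1", c(1000, 20000), "chr1", c(10000, 10000),
                   contacts = c(4, 6))
  ann <- annotate_manual(loops,
    left_e = list("E1", "E2"),
    right_e = list("E2", "E3")
  )
  cl <- build_clusters(ann)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$n_loops, 2L)
  expect_equal(cl$enhancer_count, 3L)   # E1, E2, E3 unique
  expect_equal(cl$contacts_total, 10L)

  # no sharing -> two clusters
  ann2 <- annotate_manual(loops, left_e = list("E1", "E3"), right_e = list("E2", "E4"))
  expect_equal(nrow(build_clusters(ann2)), 2)

  # a loop touching nothing is a singleton cluster
  ann3 <- annotate_manual(loops[1, ], left_e = list(character(0)),
                          right_e = list(character(0)))
  cl3 <- build_clusters(ann3)
  expect_equal(cl3$n_loops, 1L)
  expect_equal(cl3$enhancer_count, 0L)
  expect_equal(cl3$span_bp, cl3$end - cl3$start)
})

test_that("cluster metrics follow the printed definitions", {
  loops <- mk_loop("chr1", c(1000, 5500), "chr1", c(5000, 9000),
                   contacts = c(4, 6))
  ann <- annotate_manual(loops, left_e = list("E1", "E2"), right_e = list("E2", "E3"))
  cl <- build_clusters(ann)
  expect_equal(cl$contacts_total, 10L)
  expect_equal(cl$span_bp, 10000L - 1000L)
  expect_equal(cluster_metrics(ann, cl$loop_idx[[1]]),
               dplyr::select(tibble::as_tibble(cl), enhancer_count, n_loops,
                             contacts_total, span_bp))

  # trans-chromosomal cluster: span undefined
  loops_t <- mk_loop("chr1", 1000, "chr2", 5000)
  ann_t <- annotate_manual(loops_t, left_e = list("E1"), right_e = list("E2"))
  expect_true(is.na(build_clusters(ann_t)$span_bp))
})

test_that("cluster partition matches the transitive-closure oracle on random loops", {
  withr::local_seed(41)
  for (trial in 1:10) {
    n <- 40
    pool <- c(paste0("E", 1:12), paste0("g", 1:8))
    id_sets <- lapply(seq_len(n), function(i) {
      k <- sample(0:3, 1)
      if (k == 0) character(0) else sample(pool, k)
    })
    loops <- mk_loop("chr1", sample.int(1e6, n), "chr1", sample.int(1e6, n),
                     contacts = sample.int(10, n, replace = TRUE))
    ann <- annotate_manual(
      loops,
      left_e = lapply(id_sets, function(s) grep("^E", s, value = TRUE)),
      right_e = rep(list(character(0)), n),
      left_g = lapply(id_sets, function(s) grep("^g", s, value = TRUE)),
      right_g = rep(list(character(0)), n)
    )
    cl <- build_clusters(ann)

    membership <- integer(n)
    for (ci in seq_len(nrow(cl))) membership[cl$loop_idx[[ci]]] <- ci
    expect_equal(canonical_partition(membership),
                 canonical_partition(oracle_components(id_sets)))

    # metrics recompute exactly from raw loops; span bounds member loops
    for (ci in seq_len(nrow(cl))) {
      expect_equal(
        cluster_metrics(ann, cl$loop_idx[[ci]]),
        dplyr::select(tibble::as_tibble(cl[ci, ]), enhancer_count, n_loops,
                      contacts_total, span_bp)
      )
      member_spans <- vapply(cl$loop_idx[[ci]], function(i) {
        max(ann$end1[i], ann$end2[i]) - min(ann$start1[i], ann$start2[i])
      }, numeric(1))
      expect_gte(cl$span_bp[ci], max(member_spans))
    }
  }
})

test_that("target genes require strict FPKM > threshold and known expression", {
  loops <- mk_loop("chr1", 1000, "chr1", 5000)
  ann <- annotate_manual(loops, left_e = list("E1"), right_e = list(character(0)),
                         right_g = list(c("gA", "gB", "gC")))
  cl <- build_clusters(ann)
  expr <- tibble::tibble(gene_id = c("gA", "gB"), fpkm = c(2.0, 15))
  tg <- assign_target_genes(cl, expr)
  # gA at exactly 2.0 excluded (strict >); gC absent from the table -> 0
  expect_equal(tg$target_genes[[1]], "gB")
  expect_equal(tg$max_target_fpkm, 15)
})

test_that("class comparisons: perfect separation and identical distributions", {
  loops <- mk_loop("chr1", c(1, 2, 3, 4) * 1e5, "chr1", c(1, 2, 3, 4) * 1e5 + 5e4,
                   contacts = c(50, 60, 2, 3))
  ann <- annotate_manual(loops,
    left_e = list("A1", "A2", "R1", "R2"),
    right_e = rep(list(character(0)), 4)
  )
  cl <- build_clusters(ann)
  classes <- tibble::tibble(enhancer_id = c("A1", "A2", "R1", "R2"),
                            class = c("aSE", "aSE", "rEh", "rEh"))
  cl <- classify_clusters(cl, classes)
  cmp <- suppressWarnings(compare_cluster_classes(cl))
  row <- dplyr::filter(cmp$pairwise, label_a == "aSE", label_b == "rEh",
                       metric == "contacts_total")
  # every aSE-cluster contact count beats every rEh one: U is extreme
  expect_equal(row$statistic, 4)

  # identical metric distributions give p = 1
  cl_same <- classify_clusters(cl, tibble::tibble(
    enhancer_id = c("A1", "A2", "R1", "R2"),
    class = c("aSE", "rEh", "aSE", "rEh")
  ))
  cl_same$contacts_total <- c(5L, 5L, 5L, 5L)
  cl_same$span_bp <- rep(1000L, 4)
  cl_same$n_loops <- rep(1L, 4)
  cl_same$enhancer_count <- rep(1L, 4)
  cmp_same <- suppressWarnings(compare_cluster_classes(cl_same))
  expect_true(all(cmp_same$pairwise$p_value == 1))
})

test_that("aSE-containing clusters out-contact rEh-only clusters on synthetic data", {
  b <- get_small_bundle()
  res <- get_small_pipeline()
  ann <- annotate_loop_arms(b$loops, res$enhancers, b$tss)
  cl <- classify_clusters(build_clusters(ann), res$classes)
  ase_contacts <- cl$contacts_total[cl$contains_aSE]
  reh_only <- cl$contacts_total[cl$contains_rEh & !cl$contains_aSE &
                                  !cl$contains_dSE & !cl$contains_cSE]
  expect_gt(stats::median(ase_contacts), stats::median(reh_only))

  # every loop belongs to exactly one cluster
  expect_setequal(unlist(cl$loop_idx), seq_len(nrow(b$loops)))
  expect_equal(sum(lengths(cl$loop_idx)), nrow(b$loops))
})
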