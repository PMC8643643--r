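#' Annotate loop arms with enhancers and TSSs
#'
#' Intersects the left and right arm of every loop separately with the active
#' enhancers and with the TSS points, allowing a `window_bp` gap (1 kb by
#' default, the `bedtools window` default used for loop-arm intersection).
#'
#' @param loops Loop tibble ([read_bedpe()] layout).
#' @param enhancers Active-enhancer tibble with `enhancer_id`.
#' @param tss TSS tibble (`gene_id`, `chrom`, `position`).
#' @param window_bp Gap tolerance in bp (default 1000).
#' @return `loops` with four added list columns: `left_enhancers`,
#'   `right_enhancers`, `left_genes`, `right_genes`.
#' @export
annotate_loop_arms <- function(loops, enhancers, tss, window_bp = 1000) {
  loops <- as_tibble(loops)
  arm_ids <- function(arm_chrom, arm_start, arm_end, targets, id_col) {
    arms <- tibble(chrom = arm_chrom, start = arm_start, end = arm_end)
    hits <- overlap_pairs(arms, targets, window_bp = window_bp)
    ids <- vector("list", nrow(arms))
    for (i in seq_along(ids)) ids[[i]] <- character(0)
    if (nrow(hits) > 0) {
      sp <- split(targets[[id_col]][hits$idx_b], hits$idx_a)
      ids[as.integer(names(sp))] <- map(sp, function(v) sort(unique(v)))
    }
    ids
  }
  tss_iv <- tibble(gene_id = tss$gene_id, chrom = tss$chrom,
                   start = tss$position, end = tss$position + 1L)
  mutate(
    loops,
    left_enhancers = arm_ids(loops$chrom1, loops$start1, loops$end1, enhancers, "enhancer_id"),
    right_enhancers = arm_ids(loops$chrom2, loops$start2, loops$end2, enhancers, "enhancer_id"),
    left_genes = arm_ids(loops$chrom1, loops$start1, loops$end1, tss_iv, "gene_id"),
    right_genes = arm_ids(loops$chrom2, loops$start2, loops$end2, tss_iv, "gene_id")
  )
}

#' Group loops into chromatin clusters
#'
#' Two loops belong to the same cluster when they touch the same enhancer or
#' the same TSS on either arm (directly or through a chain of such sharing);
#' clusters are the connected components of that graph. Loops touching
#' nothing form singleton clusters. Per-cluster metrics follow the printed
#' definitions: enhancer count is the number of unique enhancers, contacts
#' the sum over member loops, and span `max(end) - min(start)` over all
#' member loop arms (NA for clusters spanning several chromosomes).
#'
#' @param annotated_loops Output of [annotate_loop_arms()].
#' @return A tibble classed `chromatin_clusters`, one row per cluster,
#'   ordered by (`chrom`, `start`): `cluster_id`, `chrom` (NA when
#'   trans-chromosomal), `start`, `end`, `span_bp`, `n_loops`,
#'   `enhancer_count`, `contacts_total`, and list columns `loop_idx`,
#'   `enhancer_ids`, `gene_ids`.
#' @export
build_clusters <- function(annotated_loops) {
  al <- annotated_loops
  n <- nrow(al)
  if (n == 0) {
    out <- tibble(
      cluster_id = character(), chrom = character(), start = integer(),
      end = integer(), span_bp = integer(), n_loops = integer(),
      enhancer_count = integer(), contacts_total = integer(),
      loop_idx = list(), enhancer_ids = list(), gene_ids = list()
    )
    return(structure(out, class = c("chromatin_clusters", class(tibble()))))
  }
  loop_ids <- map(seq_len(n), function(i) {
    unique(c(
      if (length(al$left_enhancers[[i]])) paste0("E::", al$left_enhancers[[i]]),
      if (length(al$right_enhancers[[i]])) paste0("E::", al$right_enhancers[[i]]),
      if (length(al$left_genes[[i]])) paste0("G::", al$left_genes[[i]]),
      if (length(al$right_genes[[i]])) paste0("G::", al$right_genes[[i]])
    ))
  })
  # bipartite loop--feature graph; loop components are the clusters
  loop_v <- paste0("L::", seq_len(n))
  feat_v <- unique(unlist(loop_ids))
  edges <- unlist(map(seq_len(n), function(i) {
    ids <- loop_ids[[i]]
    if (length(ids) == 0) return(NULL)
    rbind(loop_v[i], ids)
  }))
  g <- igraph::make_empty_graph(directed = FALSE) |>
    igraph::add_vertices(length(loop_v) + length(feat_v), name = c(loop_v, feat_v))
  if (!is.null(edges)) {
    g <- igraph::add_edges(g, match(edges, c(loop_v, feat_v)))
  }
  comp <- igraph::components(g)$membership[seq_len(n)]

  clusters <- map(split(seq_len(n), comp), function(idx) {
    arm_chroms <- c(al$chrom1[idx], al$chrom2[idx])
    arm_starts <- c(al$start1[idx], al$start2[idx])
    arm_ends <- c(al$end1[idx], al$end2[idx])
    single_chrom <- length(unique(arm_chroms)) == 1
    enh <- sort(unique(unlist(c(al$left_enhancers[idx], al$right_enhancers[idx]))))
    genes <- sort(unique(unlist(c(al$left_genes[idx], al$right_genes[idx]))))
    tibble(
      chrom = if (single_chrom) arm_chroms[1] else NA_character_,
      start = min(arm_starts),
      end = max(arm_ends),
      span_bp = if (single_chrom) max(arm_ends) - min(arm_starts) else NA_integer_,
      n_loops = length(idx),
      enhancer_count = length(enh),
      contacts_total = sum(al$contacts[idx]),
      loop_idx = list(idx),
      enhancer_ids = list(enh),
      gene_ids = list(genes),
      sort_chrom = min(arm_chroms)
    )
  })
  out <- list_rbind(clusters) |>
    arrange(.data$sort_chrom, .data$start) |>
    select(-"sort_chrom") |>
    mutate(cluster_id = sprintf("cluster_%04d", row_number()), .before = 1)
  structure(out, class = c("chromatin_clusters", class(tibble())))
}

#' Recompute the metrics of one cluster from its member loops
#'
#' Utility mirroring the stored cluster metrics from raw loop records;
#' useful for integrity checks.
#'
#' @param loops The (annotated) loop tibble the clusters were built from.
#' @param loop_idx Integer indices of the member loops.
#' @return A one-row tibble with `enhancer_count`, `n_loops`,
#'   `contacts_total`, `span_bp`.
#' @export
cluster_metrics <- function(loops, loop_idx) {
  arm_chroms <- c(loops$chrom1[loop_idx], loops$chrom2[loop_idx])
  single <- length(unique(arm_chroms)) == 1
  enh <- unique(unlist(c(loops$left_enhancers[loop_idx], loops$right_enhancers[loop_idx])))
  tibble(
    enhancer_count = length(enh),
    n_loops = length(loop_idx),
    contacts_total = sum(loops$contacts[loop_idx]),
    span_bp = if (single) {
      max(c(loops$end1[loop_idx], loops$end2[loop_idx])) -
        min(c(loops$start1[loop_idx], loops$start2[loop_idx]))
    } else {
      NA_integer_
    }
  )
}

#' Assign expressed target genes to clusters
#'
#' Every gene whose TSS touches a cluster (i.e. appears among the cluster's
#' annotated gene ids) and whose expression is strictly above `fpkm_min`
#' becomes a target gene of all enhancers in that cluster. Genes absent from
#' the expression table count as unexpressed.
#'
#' @param clusters `chromatin_clusters` tibble.
#' @param expression Expression tibble (`gene_id`, `fpkm`).
#' @param fpkm_min Expression threshold (strict; default 2).
#' @return `clusters` with added list column `target_genes` and numeric
#'   columns `n_targets`, `max_target_fpkm` (NA when no targets).
#' @export
assign_target_genes <- function(clusters, expression, fpkm_min = 2) {
  fpkm <- setNames(expression$fpkm, expression$gene_id)
  tg <- map(clusters$gene_ids, function(genes) {
    v <- fpkm[genes]
    v[is.na(v)] <- 0
    genes[v > fpkm_min]
  })
  mutate(
    clusters,
    target_genes = tg,
    n_targets = lengths(tg),
    max_target_fpkm = map_dbl(tg, function(g) {
      if (length(g) == 0) NA_real_ else max(fpkm[g])
    })
  )
}

#' Label clusters by the enhancer classes they contain
#'
#' Labels are non-exclusive: a cluster is "aSE-containing" as soon as it
#' contains one aSE, and may simultaneously carry the other labels.
#'
#' @param clusters `chromatin_clusters` tibble.
#' @param classes `enhancer_classes` tibble from [classify_enhancers()].
#' @return `clusters` with logical columns `contains_aSE`, `contains_dSE`,
#'   `contains_cSE`, `contains_rEh`.
#' @export
classify_clusters <- function(clusters, classes) {
  lookup <- setNames(as.character(classes$class), classes$enhancer_id)
  contains <- function(lbl) {
    map_lgl(clusters$enhancer_ids, function(ids) lbl %in% lookup[ids])
  }
  mutate(
    clusters,
    contains_aSE = contains("aSE"),
    contains_dSE = contains("dSE"),
    contains_cSE = contains("cSE"),
    contains_rEh = contains("rEh")
  )
}

#' Compare cluster metrics between enhancer-class labels
#'
#' For each non-exclusive cluster label with at least one cluster, collects
#' the distributions of span, contacts, loop count, enhancer count and
#' target-gene expression (all target genes pooled, and the per-cluster
#' maximum), and computes pairwise two-sided rank-sum p-values between
#' labels for every metric.
#'
#' @param clusters Output of [classify_clusters()] (after
#'   [assign_target_genes()] if expression metrics are wanted).
#' @param expression Expression tibble (`gene_id`, `fpkm`); optional, needed
#'   for the expression metrics.
#' @return A list with `summary` (per label x metric: n, median) and
#'   `pairwise` (label_a, label_b, metric, statistic, p_value).
#' @export
compare_cluster_classes <- function(clusters, expression = NULL) {
  labels <- c("aSE", "dSE", "cSE", "rEh")
  label_cols <- paste0("contains_", labels)
  present <- labels[map_lgl(label_cols, function(cl) any(clusters[[cl]]))]
  if (length(setdiff(labels, present)) > 0) {
    warn(paste0("no clusters for label(s): ",
                paste(setdiff(labels, present), collapse = ", ")))
  }
  fpkm <- if (!is.null(expression)) setNames(expression$fpkm, expression$gene_id) else NULL

  metric_values <- function(lbl, metric) {
    sub <- clusters[clusters[[paste0("contains_", lbl)]], , drop = FALSE]
    switch(metric,
      span_bp = as.numeric(sub$span_bp[!is.na(sub$span_bp)]),
      contacts_total = as.numeric(sub$contacts_total),
      n_loops = as.numeric(sub$n_loops),
      enhancer_count = as.numeric(sub$enhancer_count),
      target_fpkm = as.numeric(unlist(map(sub$target_genes, function(g) fpkm[g]))),
      max_target_fpkm = as.numeric(sub$max_target_fpkm[!is.na(sub$max_target_fpkm)])
    )
  }
  metrics <- c("span_bp", "contacts_total", "n_loops", "enhancer_count")
  if (!is.null(fpkm) && "target_genes" %in% names(clusters)) {
    metrics <- c(metrics, "target_fpkm", "max_target_fpkm")
  }

  summary_tbl <- list_rbind(map(present, function(lbl) {
    list_rbind(map(metrics, function(m) {
      v <- metric_values(lbl, m)
      tibble(label = lbl, metric = m, n = length(v),
             median = if (length(v)) stats::median(v) else NA_real_)
    }))
  }))

  pairs <- utils::combn(present, 2, simplify = FALSE)
  pairwise_tbl <- list_rbind(map(pairs, function(pr) {
    list_rbind(map(metrics, function(m) {
      va <- metric_values(pr[1], m)
      vb <- metric_values(pr[2], m)
      if (length(va) == 0 || length(vb) == 0) {
        return(tibble(label_a = pr[1], label_b = pr[2], metric = m,
                      statistic = NA_real_, p_value = NA_real_))
      }
      rs <- rank_sum_test(va, vb)
      tibble(label_a = pr[1], label_b = pr[2], metric = m,
             statistic = rs$statistic, p_value = rs$p_value)
    }))
  }))
  list(summary = summary_tbl, pairwise = pairwise_tbl)
}
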