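#' Configuration for the synthetic enhancer-landscape generator
#'
#' Bundles every generative parameter with its default. Defaults encode the
#' structure the classification pipeline assumes: a small high-occupancy
#' enhancer subpopulation (aSE-like isolated, dSE-like inside stitched runs),
#' cSE-like enhancers arranged in stitchable runs (gaps well under 12.5 kb),
#' a large regular-enhancer background, promoter-proximal decoy peaks for the
#' TSS-exclusion filter to catch, class-dependent factor binding and
#' footprint structure, loops preferentially anchored at high-occupancy
#' enhancers, and elevated expression for genes looped to them.
#'
#' @param seed Master seed; every random draw flows from it.
#' @param n_chroms,chrom_length Genome layout.
#' @param n_enhancers Number of planted enhancers (excluding decoys and
#'   DNase-only background peaks).
#' @param class_fractions Named fractions for aSE, dSE, cSE, rEh; must sum
#'   to 1.
#' @param n_factors Number of TF/cofactor ChIP-seq peak sets.
#' @param p_bind Per-class factor binding probabilities (high = aSE/dSE).
#' @param signal_meanlog,signal_sdlog Log-normal factor/DNase signal model.
#' @param delta_high Location shift (log scale) added to high-class signals.
#' @param h3k27ac_meanlog Log-normal H3K27ac location for run members
#'   (`run`) versus all other peaks (`other`); `h3k27ac_sdlog` its scale.
#' @param h3k27ac_sdlog See `h3k27ac_meanlog`.
#' @param footprint_lambda Poisson mean footprint count per enhancer (high /
#'   low classes).
#' @param footprint_width_mean,footprint_width_sd Normal footprint width
#'   model (bp).
#' @param loop_degree Mean number of loops anchored per enhancer (high /
#'   low).
#' @param loop_contacts_lambda Contacts per loop are `1 + Poisson(lambda)`,
#'   lambda chosen by whether a high-class enhancer anchors the loop.
#' @param expr_meanlog,expr_sdlog Log-normal FPKM model.
#' @param expr_shift_high Location shift for genes looped to high-class
#'   enhancers.
#' @param n_genes Number of genes/TSSs.
#' @param decoy_fraction Fraction (of `n_enhancers`) of promoter-proximal
#'   decoy peaks planted within the TSS exclusion zone.
#' @param background_fraction Fraction of DNase-only background peaks with
#'   no H3K27ac support.
#' @param run_size Enhancers per stitched (classic-SE) run.
#' @param tss_min_dist Minimum distance (bp) between planted enhancers and
#'   any TSS.
#' @param fasta_chrom_length Length of the small random FASTA emitted for
#'   sequence-composition tests.
#' @return A list of class `generator_config`.
#' @export
simulate_config <- function(seed = 1,
                            n_chroms = 2,
                            chrom_length = 5e7,
                            n_enhancers = 400,
                            class_fractions = c(aSE = 0.05, dSE = 0.02, cSE = 0.13, rEh = 0.80),
                            n_factors = 12,
                            p_bind = c(high = 0.85, cSE = 0.45, rEh = 0.25),
                            signal_meanlog = 0,
                            signal_sdlog = 0.5,
                            delta_high = 1.5,
                            h3k27ac_meanlog = c(run = 2.5, other = 1),
                            h3k27ac_sdlog = 0.4,
                            footprint_lambda = c(high = 6, low = 2),
                            footprint_width_mean = c(high = 18, low = 12),
                            footprint_width_sd = 3,
                            loop_degree = c(high = 5, low = 1),
                            loop_contacts_lambda = c(high = 8, low = 2),
                            expr_meanlog = 1,
                            expr_sdlog = 0.7,
                            expr_shift_high = 1,
                            n_genes = 150,
                            decoy_fraction = 0.05,
                            background_fraction = 0.10,
                            run_size = 4,
                            tss_min_dist = 5000,
                            fasta_chrom_length = 3000) {
  cfg <- as.list(environment())
  if (abs(sum(class_fractions) - 1) > 1e-9) {
    abort("class_fractions must sum to 1")
  }
  if (any(p_bind < 0 | p_bind > 1)) {
    abort("p_bind entries must be probabilities in [0, 1]")
  }
  if (any(c(footprint_lambda, footprint_width_mean, loop_degree,
            loop_contacts_lambda) <= 0)) {
    abort("all rates/means must be positive")
  }
  structure(cfg, class = "generator_config")
}

#' Generate a synthetic enhancer landscape with planted truth
#'
#' Produces, fully in memory, every input the classification pipeline
#' consumes: DNase and H3K27ac peaks (including promoter-proximal decoys and
#' DNase-only background), per-factor ChIP-seq peaks, annotated footprints
#' plus a consensus set, loops with contact counts, a TSS table, an
#' expression table, a small random FASTA, and the planted per-enhancer
#' truth. Identical seeds yield identical bundles.
#'
#' @param config A `generator_config` from [simulate_config()].
#' @return A list of class `synthetic_bundle` with elements `dnase`,
#'   `h3k27ac`, `factors` (named list of peak tibbles), `footprints`,
#'   `consensus`, `loops`, `tss`, `expression`, `genome`, `truth`, `runs`,
#'   `config`.
#' @export
simulate_bundle <- function(config = simulate_config()) {
  stopifnot(inherits(config, "generator_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")

  chroms <- paste0("chr", seq_len(config$n_chroms))

  ## ---- class counts ----
  n <- config$n_enhancers
  n_ase <- round(n * config$class_fractions[["aSE"]])
  n_dse <- round(n * config$class_fractions[["dSE"]])
  n_cse <- round(n * config$class_fractions[["cSE"]])
  n_reh <- n - n_ase - n_dse - n_cse
  n_decoy <- round(n * config$decoy_fraction)
  n_bg <- round(n * config$background_fraction)

  ## ---- block layout ----
  # the genome is tiled into 2 Mb blocks; each stitched run and each isolated
  # aSE claims a whole block, guaranteeing > 1 Mb separation between runs and
  # aSEs; rEh and background peaks share the remaining blocks on a coarse
  # grid (>= 15 kb spacing) so they can never stitch into a run-sized region
  block_size <- 2e6
  per_chrom <- floor(config$chrom_length / block_size)
  blocks <- tibble(
    chrom = rep(chroms, each = per_chrom),
    start = rep((seq_len(per_chrom) - 1) * block_size, times = length(chroms))
  )
  n_runs <- ceiling((n_cse + n_dse) / config$run_size)
  n_blocks_needed <- n_runs + n_ase
  if (n_blocks_needed + 2 > nrow(blocks)) {
    abort(sprintf(
      "infeasible placement: %d blocks needed, %d available (reduce n_enhancers or grow the genome)",
      n_blocks_needed, nrow(blocks)
    ))
  }
  block_order <- sample(nrow(blocks))
  run_blocks <- blocks[block_order[seq_len(n_runs)], ]
  ase_blocks <- blocks[block_order[n_runs + seq_len(n_ase)], ]
  filler_blocks <- blocks[block_order[setdiff(seq_along(block_order),
                                              seq_len(n_runs + n_ase))], ]

  ## ---- run member placement (cSE + dSE interleaved) ----
  run_members <- c(rep("cSE", n_cse), rep("dSE", n_dse))
  run_members <- run_members[sample(length(run_members))]
  run_id <- rep(seq_len(n_runs), each = config$run_size)[seq_along(run_members)]
  member_pos <- integer(length(run_members))
  member_chrom <- character(length(run_members))
  for (r in seq_len(n_runs)) {
    idx <- which(run_id == r)
    gaps <- round(runif(length(idx), 2000, 8000))
    pos <- run_blocks$start[r] + 9e5 + cumsum(gaps + 600)
    member_pos[idx] <- pos
    member_chrom[idx] <- run_blocks$chrom[r]
  }

  ## ---- aSE placement: one per claimed block, centred with jitter ----
  ase_pos <- as.integer(ase_blocks$start + 1e6 + round(runif(n_ase, -2e5, 2e5)))
  ase_chrom <- ase_blocks$chrom

  ## ---- rEh + background placement on a jittered grid in filler blocks ----
  n_filler <- n_reh + n_bg
  slots_per_block <- ceiling(n_filler / nrow(filler_blocks))
  slot_pitch <- floor(1.4e6 / slots_per_block)
  if (slot_pitch < 15000) {
    abort("infeasible placement: filler blocks too crowded (grow the genome)")
  }
  filler_idx <- rep(seq_len(nrow(filler_blocks)), each = slots_per_block)[seq_len(n_filler)]
  slot_in_block <- unlist(map(table(filler_idx), seq_len), use.names = FALSE)
  filler_pos <- as.integer(
    filler_blocks$start[filler_idx] + 3e5 + (slot_in_block - 1) * slot_pitch +
      round(runif(n_filler, 0, slot_pitch - 14000))
  )
  filler_chrom <- filler_blocks$chrom[filler_idx]
  shuffle <- sample(n_filler)
  reh_take <- shuffle[seq_len(n_reh)]
  bg_take <- shuffle[n_reh + seq_len(n_bg)]

  ## ---- assemble enhancer truth table ----
  truth <- bind_rows(
    tibble(class = run_members, chrom = member_chrom, center = member_pos,
           run_id = run_id),
    tibble(class = "aSE", chrom = ase_chrom, center = ase_pos, run_id = NA_integer_),
    tibble(class = "rEh", chrom = filler_chrom[reh_take],
           center = filler_pos[reh_take], run_id = NA_integer_)
  )
  truth <- mutate(
    truth,
    is_high = .data$class %in% c("aSE", "dSE"),
    width = pmax(as.integer(round(rnorm(nrow(truth),
                                        ifelse(.data$is_high, 500, 300),
                                        ifelse(.data$is_high, 50, 40)))), 150L),
    start = as.integer(.data$center - .data$width %/% 2),
    end = .data$start + .data$width
  )
  truth <- arrange(truth, .data$chrom, .data$start)
  truth <- mutate(truth, enhancer_id = sprintf("enh_%05d", row_number()))

  ## ---- TSS placement (>= tss_min_dist from every enhancer) ----
  occupied <- truth
  tss_pos <- integer(config$n_genes)
  tss_chrom <- sample(chroms, config$n_genes, replace = TRUE)
  for (g in seq_len(config$n_genes)) {
    for (try in 1:200) {
      cand <- round(runif(1, 1e5, config$chrom_length - 1e5))
      same <- occupied[occupied$chrom == tss_chrom[g], , drop = FALSE]
      d <- if (nrow(same)) min(pmax(same$start - cand, cand - same$end, 0)) else Inf
      prev <- tss_pos[seq_len(g - 1)][tss_chrom[seq_len(g - 1)] == tss_chrom[g]]
      dtss <- if (length(prev)) min(abs(prev - cand)) else Inf
      if (d >= config$tss_min_dist + 2600 && dtss >= 20000) {
        tss_pos[g] <- as.integer(cand)
        break
      }
    }
    if (tss_pos[g] == 0L) abort("infeasible placement: could not seat all TSSs")
  }
  tss <- tibble(
    gene_id = sprintf("gene_%04d", seq_len(config$n_genes)),
    chrom = tss_chrom,
    position = tss_pos,
    strand = sample(c("+", "-"), config$n_genes, replace = TRUE)
  ) |>
    arrange(.data$chrom, .data$position)

  ## ---- decoy peaks inside the TSS exclusion zone ----
  decoy_gene <- sample(nrow(tss), n_decoy, replace = n_decoy > nrow(tss))
  decoy_width <- pmax(as.integer(round(rnorm(n_decoy, 300, 40))), 150L)
  decoy_center <- tss$position[decoy_gene] + round(runif(n_decoy, -1500, 1500))
  decoys <- tibble(
    class = "decoy", chrom = tss$chrom[decoy_gene],
    center = as.integer(decoy_center), run_id = NA_integer_,
    is_high = FALSE, width = decoy_width,
    start = as.integer(decoy_center - decoy_width %/% 2)
  ) |>
    mutate(end = .data$start + .data$width,
           enhancer_id = sprintf("decoy_%03d", row_number()))

  ## ---- background DNase-only peaks ----
  bg_width <- pmax(as.integer(round(rnorm(n_bg, 300, 40))), 150L)
  background <- tibble(
    class = "background", chrom = filler_chrom[bg_take],
    center = filler_pos[bg_take], run_id = NA_integer_,
    is_high = FALSE, width = bg_width,
    start = as.integer(filler_pos[bg_take] - bg_width %/% 2)
  ) |>
    mutate(end = .data$start + .data$width,
           enhancer_id = sprintf("bg_%03d", row_number()))

  all_sites <- bind_rows(truth, decoys, background)

  ## ---- DNase peaks (every site) ----
  dnase <- peak_table(
    all_sites$chrom, all_sites$start, all_sites$end, all_sites$enhancer_id,
    signal = rlnorm(nrow(all_sites),
                    config$signal_meanlog + config$delta_high * all_sites$is_high,
                    config$signal_sdlog),
    label = "DNase"
  )

  ## ---- H3K27ac peaks (all but background) ----
  k27_sites <- bind_rows(truth, decoys)
  in_run <- !is.na(k27_sites$run_id)
  h3k27ac <- peak_table(
    k27_sites$chrom, pmax(k27_sites$start - 400L, 0L), k27_sites$end + 400L,
    paste0("k27_", k27_sites$enhancer_id),
    signal = rlnorm(nrow(k27_sites),
                    ifelse(in_run, config$h3k27ac_meanlog[["run"]],
                           config$h3k27ac_meanlog[["other"]]),
                    config$h3k27ac_sdlog),
    label = "H3K27ac"
  )

  ## ---- factor ChIP-seq peaks ----
  p_by_class <- c(
    aSE = config$p_bind[["high"]], dSE = config$p_bind[["high"]],
    cSE = config$p_bind[["cSE"]], rEh = config$p_bind[["rEh"]],
    decoy = config$p_bind[["rEh"]]
  )
  factor_sites <- bind_rows(truth, decoys)
  factors <- list()
  bind_mat <- matrix(FALSE, nrow(truth), config$n_factors,
                     dimnames = list(truth$enhancer_id, NULL))
  for (f in seq_len(config$n_factors)) {
    lab <- sprintf("factor_%02d", f)
    bound <- runif(nrow(factor_sites)) < p_by_class[factor_sites$class]
    fs <- factor_sites[bound, , drop = FALSE]
    w <- pmax(as.integer(round(rnorm(nrow(fs), 200, 30))), 80L)
    factors[[lab]] <- peak_table(
      fs$chrom,
      as.integer(fs$center - w %/% 2),
      as.integer(fs$center - w %/% 2) + w,
      paste0(lab, "_", fs$enhancer_id),
      signal = rlnorm(nrow(fs),
                      config$signal_meanlog + config$delta_high * fs$is_high,
                      config$signal_sdlog),
      label = lab
    )
    bind_mat[, f] <- truth$enhancer_id %in% fs$enhancer_id
  }
  colnames(bind_mat) <- names(factors)

  ## ---- footprints + consensus ----
  dbd_pool <- c("NR", "C2H2", "bZIP", "HMG", "bHLH", "Forkhead")
  fp_rows <- list()
  cons_rows <- list()
  fp_counter <- 0L
  for (i in seq_len(nrow(truth))) {
    hi <- truth$is_high[i]
    count <- rpois(1, if (hi) config$footprint_lambda[["high"]] else config$footprint_lambda[["low"]])
    if (count == 0) next
    slot <- (truth$end[i] - truth$start[i]) %/% count
    for (k in seq_len(count)) {
      fp_counter <- fp_counter + 1L
      w <- max(5L, as.integer(round(rnorm(
        1,
        if (hi) config$footprint_width_mean[["high"]] else config$footprint_width_mean[["low"]],
        config$footprint_width_sd
      ))))
      w <- min(w, max(slot - 2L, 5L))
      s <- truth$start[i] + (k - 1L) * slot +
        as.integer(floor(runif(1, 0, max(slot - w, 1))))
      fam <- if (hi) {
        sample(dbd_pool, 1, prob = c(0.4, 0.3, 0.075, 0.075, 0.075, 0.075))
      } else {
        sample(dbd_pool, 1)
      }
      bs <- rnorm(1, 12 + 1.5 * hi, 2)
      rows <- tibble(chrom = truth$chrom[i], start = s, end = s + w,
                     motif_id = paste0("motif_", fam, "_1"),
                     dbd_family = fam, bitscore = round(bs, 3))
      if (runif(1) < 0.3) {
        fam2 <- sample(setdiff(dbd_pool, fam), 1)
        rows <- bind_rows(rows, tibble(
          chrom = truth$chrom[i], start = s, end = s + w,
          motif_id = paste0("motif_", fam2, "_1"),
          dbd_family = fam2, bitscore = round(bs - abs(rnorm(1, 2, 0.5)), 3)
        ))
      }
      fp_rows[[fp_counter]] <- rows
      if (runif(1) < 0.9) {
        pad <- as.integer(round(runif(1, 0, 4)))
        cons_rows[[fp_counter]] <- tibble(
          chrom = truth$chrom[i],
          start = max(s - pad, 0L), end = s + w + pad
        )
      }
    }
  }
  footprints <- if (length(fp_rows)) {
    out <- list_rbind(fp_rows) |> arrange(.data$chrom, .data$start, .data$end)
    key <- paste(out$chrom, out$start, out$end)
    out$footprint_id <- paste0("fp_", match(key, unique(key)))
    select(out, "footprint_id", "chrom", "start", "end", "motif_id",
           "dbd_family", "bitscore")
  } else {
    tibble(footprint_id = character(), chrom = character(), start = integer(),
           end = integer(), motif_id = character(), dbd_family = character(),
           bitscore = numeric())
  }
  consensus <- if (length(cons_rows)) {
    list_rbind(cons_rows) |> arrange(.data$chrom, .data$start, .data$end)
  } else {
    tibble(chrom = character(), start = integer(), end = integer())
  }

  ## ---- loops ----
  loop_rows <- list()
  li <- 0L
  genes_by_chrom <- split(seq_len(nrow(tss)), tss$chrom)
  enh_by_chrom <- split(seq_len(nrow(truth)), truth$chrom)
  for (i in seq_len(nrow(truth))) {
    hi <- truth$is_high[i]
    d <- rpois(1, if (hi) config$loop_degree[["high"]] else config$loop_degree[["low"]])
    if (d == 0) next
    for (k in seq_len(d)) {
      li <- li + 1L
      chrom_i <- truth$chrom[i]
      to_gene <- runif(1) < 0.6
      if (to_gene) {
        cand <- genes_by_chrom[[chrom_i]]
        j <- cand[sample.int(length(cand), 1)]
        p_center <- tss$position[j]
        partner_high <- FALSE
      } else {
        cand <- setdiff(enh_by_chrom[[chrom_i]], i)
        j <- cand[sample.int(length(cand), 1)]
        p_center <- truth$center[j]
        partner_high <- truth$is_high[j]
      }
      lam <- if (hi || partner_high) config$loop_contacts_lambda[["high"]] else config$loop_contacts_lambda[["low"]]
      a1 <- as.integer(truth$center[i] - 500L)
      a2 <- as.integer(p_center - 500L)
      loop_rows[[li]] <- tibble(
        chrom1 = chrom_i, start1 = a1, end1 = a1 + 1000L,
        chrom2 = chrom_i, start2 = a2, end2 = a2 + 1000L,
        contacts = 1L + rpois(1, lam),
        anchor_enhancer = truth$enhancer_id[i],
        partner = if (to_gene) tss$gene_id[j] else truth$enhancer_id[j],
        partner_is_gene = to_gene
      )
    }
  }
  loops <- if (li > 0) {
    list_rbind(loop_rows) |>
      arrange(.data$chrom1, .data$start1, .data$start2) |>
      mutate(loop_id = sprintf("loop_%04d", row_number()), .before = 1)
  } else {
    tibble(loop_id = character(), chrom1 = character(), start1 = integer(),
           end1 = integer(), chrom2 = character(), start2 = integer(),
           end2 = integer(), contacts = integer(),
           anchor_enhancer = character(), partner = character(),
           partner_is_gene = logical())
  }

  ## ---- expression ----
  looped_high_genes <- unique(loops$partner[loops$partner_is_gene &
    loops$anchor_enhancer %in% truth$enhancer_id[truth$is_high]])
  expression <- tibble(
    gene_id = tss$gene_id,
    fpkm = round(rlnorm(
      nrow(tss),
      config$expr_meanlog + config$expr_shift_high * (tss$gene_id %in% looped_high_genes),
      config$expr_sdlog
    ), 4)
  )

  ## ---- small random FASTA for composition tests ----
  genome <- setNames(
    paste(sample(c("A", "C", "G", "T"), config$fasta_chrom_length, replace = TRUE),
          collapse = ""),
    "chrS"
  )

  ## ---- run intervals (planted classic-SE truth) ----
  run_members_tbl <- filter(truth, !is.na(.data$run_id))
  runs <- if (nrow(run_members_tbl) > 0) {
    run_members_tbl |>
      group_by(.data$run_id) |>
      summarise(chrom = dplyr::first(.data$chrom), start = min(.data$start),
                end = max(.data$end), n_members = n(), .groups = "drop")
  } else {
    tibble(run_id = integer(), chrom = character(), start = integer(),
           end = integer(), n_members = integer())
  }

  structure(
    list(
      dnase = dnase,
      h3k27ac = h3k27ac,
      factors = factors,
      footprints = footprints,
      consensus = consensus,
      loops = loops,
      tss = tss,
      expression = expression,
      genome = genome,
      truth = select(bind_rows(truth, decoys, background),
                     "enhancer_id", "class", "chrom", "start", "end",
                     "is_high", "run_id"),
      binding = bind_mat,
      runs = runs,
      config = config
    ),
    class = "synthetic_bundle"
  )
}

# canonical narrowPeak-layout tibble, sorted
peak_table <- function(chrom, start, end, name, signal, label) {
  tibble(
    chrom = chrom, start = as.integer(start), end = as.integer(end),
    name = name, score = 0, strand = ".",
    signal_value = round(signal, 4), p_value = -1, q_value = -1,
    summit_offset = -1L, label = label
  ) |>
    arrange(.data$chrom, .data$start, .data$end)
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat(sprintf(
    "<synthetic_bundle> seed %d: %d enhancers (+%d decoys, +%d background), %d factors, %d loops, %d genes\n",
    x$config$seed, sum(x$truth$class %in% c("aSE", "dSE", "cSE", "rEh")),
    sum(x$truth$class == "decoy"), sum(x$truth$class == "background"),
    length(x$factors), nrow(x$loops), nrow(x$tss)
  ))
  invisible(x)
}

#' Write a synthetic bundle to a directory of plain-text files
#'
#' Emits `dnase.narrowPeak`, `h3k27ac.narrowPeak`, one
#' `factor_XX.narrowPeak` per factor, `footprints.bed` (BED6+3),
#' `consensus.bed`, `loops.bedpe`, `tss.tsv`, `expr.tsv`, `genome.fa` and
#' `truth.json`. All files are valid inputs to the package readers.
#'
#' @param bundle A `synthetic_bundle`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_narrowpeak(bundle$dnase, file.path(dir, "dnase.narrowPeak"))
  write_narrowpeak(bundle$h3k27ac, file.path(dir, "h3k27ac.narrowPeak"))
  for (lab in names(bundle$factors)) {
    write_narrowpeak(bundle$factors[[lab]], file.path(dir, paste0(lab, ".narrowPeak")))
  }
  fp <- bundle$footprints
  readr::write_tsv(
    tibble(fp$chrom, fp$start, fp$end, fp$footprint_id, 0, ".",
           fp$motif_id, fp$dbd_family, fp$bitscore),
    file.path(dir, "footprints.bed"), col_names = FALSE, progress = FALSE
  )
  readr::write_tsv(bundle$consensus, file.path(dir, "consensus.bed"),
                   col_names = FALSE, progress = FALSE)
  lp <- bundle$loops
  readr::write_tsv(
    tibble(lp$chrom1, lp$start1, lp$end1, lp$chrom2, lp$start2, lp$end2,
           lp$loop_id, lp$contacts),
    file.path(dir, "loops.bedpe"), col_names = FALSE, progress = FALSE
  )
  readr::write_tsv(bundle$tss, file.path(dir, "tss.tsv"), progress = FALSE)
  readr::write_tsv(bundle$expression, file.path(dir, "expr.tsv"), progress = FALSE)
  writeLines(c(paste0(">", names(bundle$genome)), unname(bundle$genome)),
             file.path(dir, "genome.fa"))
  jsonlite::write_json(bundle$truth, file.path(dir, "truth.json"),
                       digits = NA, na = "null")
  invisible(dir)
}
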