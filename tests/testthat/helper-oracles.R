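# Independent brute-force oracles. Each reimplements an operation in the
# most literal way possible (all-pairs scans, transitive closures, explicit
# loops) so the vectorized/engine-backed implementations can be checked
# against them on random instances.

oracle_overlap <- function(a, b, window_bp = 0) {
  out <- list()
  k <- 0L
  for (i in seq_len(nrow(a))) {
    s <- max(a$start[i] - window_bp, 0)
    e <- a$end[i] + window_bp
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[j] && s < b$end[j] && b$start[j] < e) {
        k <- k + 1L
        out[[k]] <- c(i, j)
      }
    }
  }
  if (k == 0) {
    return(tibble::tibble(idx_a = integer(), idx_b = integer()))
  }
  m <- do.call(rbind, out)
  tibble::tibble(idx_a = m[, 1], idx_b = m[, 2])
}

# transitive merge: repeatedly fuse any two regions whose gap <= d
oracle_stitch <- function(peaks, d) {
  regions <- lapply(seq_len(nrow(peaks)), function(i) {
    list(chrom = peaks$chrom[i], start = peaks$start[i], end = peaks$end[i],
         members = i)
  })
  repeat {
    merged <- FALSE
    for (i in seq_along(regions)) {
      for (j in seq_along(regions)) {
        if (i >= j) next
        a <- regions[[i]]; b <- regions[[j]]
        if (a$chrom == b$chrom &&
            max(a$start, b$start) - min(a$end, b$end) <= d) {
          regions[[i]] <- list(
            chrom = a$chrom, start = min(a$start, b$start),
            end = max(a$end, b$end), members = c(a$members, b$members)
          )
          regions[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  df <- do.call(rbind, lapply(regions, function(r) {
    data.frame(chrom = r$chrom, start = r$start, end = r$end,
               n_peaks = length(r$members),
               total_signal = sum(peaks$signal_value[r$members]))
  }))
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# connected components of loops sharing any feature id, by boolean matrix
# transitive closure
oracle_components <- function(id_sets) {
  n <- length(id_sets)
  adj <- diag(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && length(intersect(id_sets[[i]], id_sets[[j]])) > 0) {
        adj[i, j] <- TRUE
      }
    }
  }
  repeat {
    nxt <- (adj %*% adj) > 0
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cur <- cur + 1L
      comp[adj[i, ]] <- cur
    }
  }
  comp
}

# canonical partition representation for comparing clusterings
canonical_partition <- function(membership) {
  unname(lapply(
    split(seq_along(membership), membership),
    identity
  )[order(vapply(split(seq_along(membership), membership), min, integer(1)))])
}

oracle_os <- function(raw, normalized) {
  vapply(seq_len(nrow(raw)), function(i) {
    n_bound <- sum(raw[i, ] > 0)
    n_bound * sum(normalized[i, ])
  }, numeric(1))
}

# literal walk-up-the-curve inflection scan
oracle_inflection <- function(values, half_window = 1, ref_max = NULL) {
  y <- sort(values)
  n <- length(y)
  ref <- if (is.null(ref_max)) (y[n] - y[1]) / n else (ref_max - y[1]) / n
  cutoff_rank <- n
  found <- FALSE
  for (k in seq_len(n)) {
    lo <- max(k - half_window, 1)
    hi <- min(k + half_window, n)
    slope <- (y[hi] - y[lo]) / (hi - lo)
    if (slope > ref) {
      cutoff_rank <- if (k == 1) n else k - 1
      found <- TRUE
      break
    }
  }
  list(cutoff_value = y[cutoff_rank], cutoff_rank = cutoff_rank)
}

# AUC as the pairwise probability that a positive outranks a negative
oracle_auc <- function(score, truth) {
  pos <- score[truth]
  neg <- score[!truth]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# exact two-sided rank-sum p by full enumeration of group labelings
oracle_ranksum_exact <- function(x, y) {
  n1 <- length(x)
  all_v <- c(x, y)
  r <- rank(all_v)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(all_v), n1)
  u_all <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * length(y) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
}

rand_peaks <- function(n, chroms = c("chr1", "chr2"), max_pos = 10000,
                       max_width = 300) {
  start <- sample.int(max_pos, n, replace = TRUE)
  tibble::tibble(
    chrom = sample(chroms, n, replace = TRUE),
    start = start,
    end = start + sample.int(max_width, n, replace = TRUE),
    name = paste0("p", seq_len(n)),
    signal_value = round(stats::runif(n, 0.1, 20), 3)
  ) |> dplyr::arrange(chrom, start, end)
}
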