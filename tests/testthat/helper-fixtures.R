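# Shared fixtures. The small bundle keeps unit tests fast; acceptance tests
# use the full default configuration.

small_config <- function(seed = 11) {
  simulate_config(
    seed = seed,
    n_enhancers = 120,
    n_factors = 6,
    n_genes = 60,
    chrom_length = 4e7
  )
}

.fixture_env <- new.env(parent = emptyenv())

get_small_bundle <- function(seed = 11) {
  key <- paste0("bundle_", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- simulate_bundle(small_config(seed))
  }
  .fixture_env[[key]]
}

get_small_pipeline <- function(seed = 11) {
  key <- paste0("pipeline_", seed)
  if (is.null(.fixture_env[[key]])) {
    b <- get_small_bundle(seed)
    .fixture_env[[key]] <- classify_enhancer_landscape(
      b$dnase, b$h3k27ac, b$tss, b$factors
    )
  }
  .fixture_env[[key]]
}

# tiny deterministic peak tibble builder for hand-worked examples
peaks_tbl <- function(chrom, start, end, signal = 1, name = NULL) {
  tibble::tibble(
    chrom = chrom,
    start = as.integer(start),
    end = as.integer(end),
    name = name %||% paste0("pk", seq_along(start)),
    signal_value = signal
  )
}

`%||%` <- rlang::`%||%`
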