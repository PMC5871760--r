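# Small fixture builders shared across test files.

# A hand-sized spectral-count table: values is a named list prey_id -> counts
# (one per sample, in meta order). A BirA row is added unless present.
tiny_counts <- function(values, n_replicates = 2,
                        baits = c("WT", "MUT1", "MUT2", "A2"),
                        birA_counts = NULL) {
  meta <- tidyr::expand_grid(bait = baits, replicate = seq_len(n_replicates))
  meta$sample_id <- paste(meta$bait, meta$replicate, sep = ".")
  meta <- meta[c("sample_id", "bait", "replicate")]
  n_samp <- nrow(meta)
  if (!"BirA" %in% names(values)) {
    values$BirA <- if (is.null(birA_counts)) rep(10L, n_samp) else birA_counts
  }
  counts <- tibble::tibble(prey_id = names(values))
  mat <- do.call(rbind, lapply(values, function(v) rep_len(as.integer(v), n_samp)))
  colnames(mat) <- meta$sample_id
  counts <- dplyr::bind_cols(counts, tibble::as_tibble(mat))
  list(counts = counts, meta = meta)
}

random_reference <- function(n, seed = 42) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = ""))
}
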