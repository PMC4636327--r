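# Shared fixture builders. Oracles for derived expectations live next to the
# tests that use them and are written independently of the package internals.

rand_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

substitute_at <- function(s, positions, bases = NULL) {
  v <- strsplit(s, "")[[1]]
  for (k in seq_along(positions)) {
    p <- positions[k]
    v[p] <- if (is.null(bases)) {
      setdiff(c("A", "C", "G", "T"), v[p])[1]
    } else bases[k]
  }
  paste(v, collapse = "")
}

# Minimal aligned unique-sequence table in the package's working-set shape.
make_uniques <- function(gapped, counts, sample = "s1") {
  df <- data.frame(seq_id = sprintf("u%03d", seq_along(gapped)),
                   sequence = gsub("[-.]", "", gapped),
                   total_count = as.integer(counts))
  df[[paste0("n.", sample)]] <- as.integer(counts)
  df$gapped <- gapped
  df$start_col <- 1L
  df$end_col <- nchar(gapped[1])
  df$template_id <- "t"
  df$identity <- 1
  class(df) <- c("aligned_seqs", "unique_seqs", "data.frame")
  df
}

# Small mock + matching reference alignment and trained classifier, reused by
# pipeline-level tests.
make_mock_setup <- function(n_strains = 4, seed = 7, depth = 2000,
                            primer_dropout = integer(0), copies = 1e7,
                            kit = "v2", run_seed = 11, ...) {
  spec <- synth_reference_set(n_strains, seed = seed,
                              primer_dropout = primer_dropout,
                              copies = copies)
  cfg <- seq_run_config(kit = kit, depth = depth, seed = run_seed, ...)
  pcr <- in_silico_pcr(spec)
  amp <- which(pcr$amplifiable)
  ref <- reference_alignment(
    substr(spec$strains$sequence[amp], pcr$start[amp], pcr$end[amp]),
    spec$strains$name[amp])
  model <- train_classifier(spec$taxonomy)
  list(spec = spec, cfg = cfg, ref = ref, model = model, amp = amp)
}
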