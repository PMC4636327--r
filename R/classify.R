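# Step 4: naive-Bayes k-mer taxonomic classification with bootstrap
# confidence. A sequence's distinct 8-mers vote for the genus maximizing the
# sum of log word-conditionals; confidence at each rank is the fraction of
# bootstrap word-resamples whose winning genus agrees at that rank. Ranks
# under the confidence cutoff (default 80%) are reported "unclassified", and
# sequences whose domain is not confidently Bacteria are filtered out.

TAX_RANKS <- c("domain", "phylum", "class", "order", "family", "genus")

#' Build a taxonomy reference
#'
#' @param ids sequence identifiers.
#' @param sequences ungapped DNA training sequences.
#' @param lineages character vector of 6-rank lineages
#'   `Domain;Phylum;Class;Order;Family;Genus` (trailing `;` tolerated).
#' @return A `taxonomy_reference` data.frame with one column per rank.
#' @export
taxonomy_reference <- function(ids, sequences, lineages) {
  parts <- strsplit(sub(";$", "", lineages), ";", fixed = TRUE)
  if (any(lengths(parts) != 6)) {
    stop("every lineage must have exactly 6 ranks (domain..genus)")
  }
  if (any(vapply(parts, function(p) any(!nzchar(p)), logical(1)))) {
    stop("empty rank label in lineage")
  }
  ranks <- do.call(rbind, parts)
  colnames(ranks) <- TAX_RANKS
  out <- data.frame(seq_id = ids, sequence = toupper(sequences),
                    as.data.frame(ranks, stringsAsFactors = FALSE))
  class(out) <- c("taxonomy_reference", "data.frame")
  out
}

#' Read a taxonomy reference from FASTA + lineage TSV
#'
#' The TSV holds `seq_id<TAB>Domain;Phylum;Class;Order;Family;Genus;` rows.
#'
#' @param fasta_path ungapped reference FASTA.
#' @param taxonomy_path two-column lineage TSV (no header).
#' @return A `taxonomy_reference`.
#' @export
read_taxonomy_reference <- function(fasta_path, taxonomy_path) {
  x <- Biostrings::readDNAStringSet(fasta_path)
  tx <- read.table(taxonomy_path, sep = "\t", header = FALSE,
                   col.names = c("seq_id", "lineage"),
                   stringsAsFactors = FALSE)
  i <- match(names(x), tx$seq_id)
  if (anyNA(i)) stop("taxonomy file misses lineages for some sequences")
  taxonomy_reference(names(x), as.character(x), tx$lineage[i])
}

#' Train the naive-Bayes word model
#'
#' Word priors follow `(n_w + 0.5) / (N + 1)` over the `N` training
#' sequences, and per-genus conditionals `(m_w + prior) / (M + 1)` over the
#' `M` sequences of the genus, with distinct-word presence (not multiplicity)
#' on the given strand only.
#'
#' @param ref a `taxonomy_reference` with at least 2 genera.
#' @param k word size (default 8).
#' @return A `word_model`: list with `k`, `genus_list`, `lineage` (matrix
#'   ranks x genera), `log_conditional` (4^k x genera), `word_prior`.
#' @export
train_classifier <- function(ref, k = 8L) {
  genera <- sort(unique(ref$genus))
  if (length(genera) < 2) stop("classifier training requires at least 2 genera")
  n_words <- as.integer(4^k)
  N <- nrow(ref)
  word_sets <- lapply(ref$sequence, encode_kmers, k = k)
  n_w <- tabulate(unlist(word_sets) + 1L, nbins = n_words)
  prior <- (n_w + 0.5) / (N + 1)
  logcond <- matrix(NA_real_, n_words, length(genera),
                    dimnames = list(NULL, genera))
  for (g in genera) {
    rows <- which(ref$genus == g)
    M <- length(rows)
    m_w <- tabulate(unlist(word_sets[rows]) + 1L, nbins = n_words)
    logcond[, g] <- log((m_w + prior) / (M + 1))
  }
  lin <- t(vapply(genera, function(g) {
    unlist(ref[ref$genus == g, TAX_RANKS][1, ])
  }, character(6)))
  colnames(lin) <- TAX_RANKS
  structure(list(k = k, genus_list = genera, lineage = lin,
                 log_conditional = logcond, word_prior = prior),
            class = "word_model")
}

#' @export
print.word_model <- function(x, ...) {
  cat("word_model: k =", x$k, "|", length(x$genus_list), "genera\n")
  invisible(x)
}

#' Classify a sequence with bootstrap confidence
#'
#' The full-word genus score is the sum of log conditionals over the
#' sequence's distinct words (argmax; ties to the lexicographically smallest
#' genus). Each bootstrap round resamples `floor(W/8)` of the `W` distinct
#' words with replacement and re-runs the argmax; per-rank confidence is the
#' percentage of rounds agreeing with the winner's lineage at that rank.
#' Ranks whose confidence falls below `cutoff` are labelled "unclassified"
#' (and so are all deeper ranks, keeping the lineage hierarchically
#' consistent).
#'
#' @param sequence DNA string of length >= `k`.
#' @param model a `word_model` from [train_classifier()].
#' @param bootstraps number of bootstrap rounds (default 100).
#' @param cutoff minimum confidence percentage (default 80).
#' @param seed optional integer seed for reproducible bootstraps.
#' @return List with `labels` (named, per rank), `confidence` (named, per
#'   rank, percent), `assigned_genus_raw` (full-word winner before cutoff).
#' @export
classify_sequence <- function(sequence, model, bootstraps = 100L, cutoff = 80,
                              seed = NULL) {
  words <- encode_kmers(toupper(sequence), model$k)
  if (length(words) == 0) {
    stop("sequence shorter than word size (", model$k, ")")
  }
  if (!is.null(seed)) set.seed(seed)
  lc <- model$log_conditional[words + 1L, , drop = FALSE]
  full_score <- colSums(lc)
  winner <- model$genus_list[order(-full_score, model$genus_list)][1]
  W <- length(words)
  nsub <- max(1L, W %/% 8L)
  wins <- character(bootstraps)
  for (b in seq_len(bootstraps)) {
    idx <- sample.int(W, nsub, replace = TRUE)
    sc <- colSums(lc[idx, , drop = FALSE])
    wins[b] <- model$genus_list[order(-sc, model$genus_list)][1]
  }
  win_lineage <- model$lineage[winner, ]
  conf <- vapply(TAX_RANKS, function(r) {
    100 * mean(model$lineage[wins, r] == win_lineage[r])
  }, numeric(1))
  labels <- win_lineage
  below <- which(conf < cutoff)
  if (length(below)) {
    labels[min(below):length(TAX_RANKS)] <- "unclassified"
  }
  list(labels = labels, confidence = conf, assigned_genus_raw = winner)
}

#' Classify every unique sequence
#'
#' @param uniques a `unique_seqs`/`aligned_seqs` data.frame; classification
#'   uses the ungapped `sequence` column.
#' @param model a `word_model`.
#' @param bootstraps,cutoff see [classify_sequence()].
#' @param seed integer; per-sequence seeds are derived deterministically.
#' @return data.frame `assignments`: `seq_id`, one label and one confidence
#'   column per rank (`domain`, `domain_conf`, ...), `assigned_genus_raw`.
#' @export
classify_uniques <- function(uniques, model, bootstraps = 100L, cutoff = 80,
                             seed = 1L) {
  n <- nrow(uniques)
  res <- vector("list", n)
  for (i in seq_len(n)) {
    res[[i]] <- classify_sequence(uniques$sequence[i], model,
                                  bootstraps = bootstraps, cutoff = cutoff,
                                  seed = seed + i - 1L)
  }
  out <- data.frame(seq_id = uniques$seq_id)
  for (r in TAX_RANKS) {
    out[[r]] <- vapply(res, function(x) unname(x$labels[r]), character(1))
    out[[paste0(r, "_conf")]] <- vapply(res, function(x) x$confidence[r],
                                        numeric(1))
  }
  out$assigned_genus_raw <- vapply(res, `[[`, character(1),
                                   "assigned_genus_raw")
  out
}

#' Filter sequences not confidently assigned to Bacteria
#'
#' @param uniques the working set.
#' @param assignments data.frame from [classify_uniques()].
#' @return List with `kept`, `removed`, `removed_count`, read totals.
#' @export
filter_non_bacteria <- function(uniques, assignments) {
  i <- match(uniques$seq_id, assignments$seq_id)
  if (anyNA(i)) stop("assignments missing for some sequences")
  keep <- assignments$domain[i] == "Bacteria"
  list(kept = `rownames<-`(uniques[keep, , drop = FALSE], NULL),
       removed = `rownames<-`(uniques[!keep, , drop = FALSE], NULL),
       removed_count = sum(!keep),
       reads_in = sum(uniques$total_count),
       reads_out = sum(uniques$total_count[keep]))
}

#' Write assignments in `label(confidence)` notation
#'
#' @param assignments data.frame from [classify_uniques()].
#' @param file output TSV path.
#' @export
write_assignments <- function(assignments, file) {
  lab <- vapply(seq_len(nrow(assignments)), function(i) {
    paste(vapply(TAX_RANKS, function(r) {
      sprintf("%s(%d)", assignments[[r]][i],
              as.integer(round(assignments[[paste0(r, "_conf")]][i])))
    }, character(1)), collapse = ";")
  }, character(1))
  write.table(data.frame(seq_id = assignments$seq_id, taxonomy = lab),
              file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
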