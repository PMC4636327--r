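# Step 1 of the analysis pipeline: dereplication of the joined working set,
# template-based alignment to a gapped reference 16S alignment, culling of
# sequences that fail to align (non-specific amplification, common in tissue
# samples rich in host DNA), and blunt-end trimming to a shared column span.

#' Dereplicate joined sequences
#'
#' Collapses exact duplicate sequences (case-folded) into unique records with
#' total and per-sample counts. Output is sorted by decreasing total count,
#' ties by sequence lexicographic order.
#'
#' @param joined data.frame with columns `sequence` and `sample_id`
#'   (as produced by [join_pairs()]); `sample_id` may be `NA`.
#' @return data.frame of class `unique_seqs`: `seq_id`, `sequence`,
#'   `total_count`, plus one integer column per sample
#'   (named `n.<sample_id>`).
#' @export
dereplicate <- function(joined) {
  if (nrow(joined) == 0) {
    out <- data.frame(seq_id = character(0), sequence = character(0),
                      total_count = integer(0))
    class(out) <- c("unique_seqs", "data.frame")
    return(out)
  }
  seqs <- toupper(joined$sequence)
  samples <- as.character(joined$sample_id)
  samples[is.na(samples)] <- "sample1"
  tab <- table(seqs, samples)
  total <- rowSums(tab)
  ord <- order(-total, rownames(tab))
  out <- data.frame(seq_id = sprintf("u%06d", seq_along(ord)),
                    sequence = rownames(tab)[ord],
                    total_count = as.integer(total[ord]))
  persample <- as.data.frame.matrix(tab[ord, , drop = FALSE])
  names(persample) <- paste0("n.", names(persample))
  rownames(persample) <- NULL
  out <- cbind(out, persample)
  rownames(out) <- NULL
  class(out) <- c("unique_seqs", "data.frame")
  out
}

sample_count_cols <- function(uniques) {
  grep("^n\\.", names(uniques), value = TRUE)
}

#' Read a gapped reference alignment from FASTA
#'
#' Both `-` and `.` are treated as gap characters; all records must share one
#' alignment length.
#'
#' @param path FASTA file of aligned (gapped) 16S sequences.
#' @return A `reference_alignment`: list with `template_id`, `gapped`,
#'   `ungapped`, `col_map` (list: ungapped position -> alignment column),
#'   `column_count`.
#' @export
read_reference_alignment <- function(path) {
  x <- Biostrings::readBStringSet(path)
  reference_alignment(as.character(x), names(x))
}

#' Build a reference alignment from gapped sequences
#'
#' @param gapped character vector of gapped sequences over `{A,C,G,T,-,.}`.
#' @param ids template identifiers.
#' @return A `reference_alignment` (see [read_reference_alignment()]).
#' @export
reference_alignment <- function(gapped, ids = NULL) {
  gapped <- toupper(gapped)
  ids <- ids %||% sprintf("tmpl%03d", seq_along(gapped))
  cc <- unique(nchar(gapped))
  if (length(cc) != 1) stop("reference alignment columns differ across templates")
  ungapped <- gsub("[-.]", "", gapped)
  col_map <- lapply(gapped, function(g) which(!strsplit(g, "")[[1]] %in% c("-", ".")))
  kmer_sets <- lapply(ungapped, encode_kmers, k = 8L)
  # per-template logical lookup over the 4^8 word space for fast shared-word counts
  kmer_lut <- matrix(FALSE, 65536L, length(gapped))
  for (i in seq_along(kmer_sets)) kmer_lut[kmer_sets[[i]] + 1L, i] <- TRUE
  structure(list(template_id = ids, gapped = gapped, ungapped = ungapped,
                 col_map = col_map, column_count = cc, kmer_lut = kmer_lut),
            class = "reference_alignment")
}

#' @export
print.reference_alignment <- function(x, ...) {
  cat("reference_alignment:", length(x$template_id), "templates,",
      x$column_count, "columns\n")
  invisible(x)
}

# Global (Needleman-Wunsch) alignment of query against the ungapped template,
# returning template-coordinate projection. Fast path: equal lengths are
# compared position-wise without dynamic programming.
align_one <- function(query, ref, ti) {
  tmpl <- ref$ungapped[ti]
  if (nchar(query) == nchar(tmpl)) {
    qv <- utf8ToInt(query); tv <- utf8ToInt(tmpl)
    nmatch <- sum(qv == tv)
    return(list(identity = nmatch / nchar(tmpl),
                tpos_base = strsplit(query, "")[[1]],
                tpos = seq_len(nchar(tmpl)),
                inserted = 0L))
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  al <- Biostrings::pairwiseAlignment(query, tmpl, substitutionMatrix = mat,
                                      gapOpening = 2, gapExtension = 1,
                                      type = "global")
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  tpos <- cumsum(sa != "-")
  keep <- sa != "-"                 # drop query bases inserted vs template
  list(identity = Biostrings::nmatch(al) / length(pa),
       tpos_base = pa[keep],        # '-' where the template base is deleted
       tpos = tpos[keep],
       inserted = sum(!keep & pa != "-"))
}

#' Align a unique sequence to the reference alignment
#'
#' Picks the template sharing the most distinct 8-mers with the query
#' (ties: lexicographically smallest template id), globally aligns the query
#' to the ungapped template (match +1, mismatch -1, gap open -2, gap
#' extend -1), and projects the query into the template's alignment columns,
#' dropping bases inserted relative to the template. The query is reported
#' non-alignable when identity (matches / alignment length) falls below
#' `min_identity` or the aligned template span covers less than
#' `min_coverage` of the query.
#'
#' @param sequence query DNA string.
#' @param ref a `reference_alignment`.
#' @param k k-mer size for template search (default 8).
#' @param min_identity,min_coverage cull thresholds (defaults 0.5, 0.5).
#' @return List with `alignable`; when alignable also `gapped` (full column
#'   space, `.` outside the aligned span), `start_col`, `end_col` (1-based
#'   inclusive), `template_id`, `identity`, `inserted_bases`.
#' @export
align_to_reference <- function(sequence, ref, k = 8L,
                               min_identity = 0.5, min_coverage = 0.5) {
  sequence <- toupper(sequence)
  words <- encode_kmers(sequence, k)
  if (length(words) == 0) return(list(alignable = FALSE, reason = "too-short"))
  shared <- colSums(ref$kmer_lut[words + 1L, , drop = FALSE])
  best <- which(shared == max(shared))
  ti <- best[order(ref$template_id[best])][1]
  al <- align_one(sequence, ref, ti)
  span_q <- sum(al$tpos_base != "-") / nchar(sequence)
  if (al$identity < min_identity || span_q < min_coverage) {
    return(list(alignable = FALSE, reason = "low-identity",
                template_id = ref$template_id[ti], identity = al$identity))
  }
  cols <- ref$col_map[[ti]][al$tpos]
  present <- which(al$tpos_base != "-")
  start_col <- cols[present[1]]
  end_col <- cols[present[length(present)]]
  gapped <- rep(".", ref$column_count)
  inside <- cols >= start_col & cols <= end_col
  gapped[start_col:end_col] <- "-"   # template columns absent in this span
  gapped[cols[inside]] <- al$tpos_base[inside]
  # template gap columns inside the span stay '-'
  list(alignable = TRUE,
       gapped = paste(gapped, collapse = ""),
       start_col = start_col, end_col = end_col,
       template_id = ref$template_id[ti],
       identity = al$identity,
       inserted_bases = al$inserted)
}

#' Align all unique sequences and cull non-specific ones
#'
#' @param uniques a `unique_seqs` data.frame from [dereplicate()].
#' @param ref a `reference_alignment`.
#' @param ... passed to [align_to_reference()].
#' @return List with `kept` (an `aligned_seqs` data.frame: the unique columns
#'   plus `gapped`, `start_col`, `end_col`, `template_id`, `identity`),
#'   `culled` (unique rows that failed), and `culled_count`.
#' @export
cull_nonspecific <- function(uniques, ref, ...) {
  n <- nrow(uniques)
  res <- vector("list", n)
  for (i in seq_len(n)) {
    res[[i]] <- align_to_reference(uniques$sequence[i], ref, ...)
  }
  ok <- vapply(res, `[[`, logical(1), "alignable")
  kept <- uniques[ok, , drop = FALSE]
  if (any(ok)) {
    kept$gapped <- vapply(res[ok], `[[`, character(1), "gapped")
    kept$start_col <- vapply(res[ok], `[[`, integer(1), "start_col")
    kept$end_col <- vapply(res[ok], `[[`, integer(1), "end_col")
    kept$template_id <- vapply(res[ok], `[[`, character(1), "template_id")
    kept$identity <- vapply(res[ok], `[[`, numeric(1), "identity")
  } else {
    kept$gapped <- character(0); kept$start_col <- integer(0)
    kept$end_col <- integer(0); kept$template_id <- character(0)
    kept$identity <- numeric(0)
  }
  rownames(kept) <- NULL
  class(kept) <- c("aligned_seqs", class(uniques))
  list(kept = kept,
       culled = uniques[!ok, , drop = FALSE],
       culled_count = sum(!ok))
}

#' Trim aligned sequences to blunt ends
#'
#' Truncates every aligned sequence to the common column span
#' `[max(start_col), min(end_col)]` so that all sequences cover identical
#' alignment columns, as required by distance-based clustering.
#'
#' @param aligned an `aligned_seqs` data.frame from [cull_nonspecific()].
#' @return List with `trimmed` (same shape; `gapped` now holds only the
#'   common span, `start_col`/`end_col` updated) and `removed_count`
#'   (sequences whose span did not cover the common window).
#' @export
trim_blunt <- function(aligned) {
  if (nrow(aligned) == 0) stop("no aligned sequences to trim")
  L <- max(aligned$start_col)
  R <- min(aligned$end_col)
  if (R < L) stop("aligned sequences share no common column span")
  covers <- aligned$start_col <= L & aligned$end_col >= R
  out <- aligned[covers, , drop = FALSE]
  out$gapped <- substr(out$gapped, L, R)
  out$start_col <- L
  out$end_col <- R
  rownames(out) <- NULL
  list(trimmed = out, removed_count = sum(!covers),
       start_col = L, end_col = R)
}

#' Re-dereplicate aligned sequences after trimming
#'
#' Blunt trimming can make previously distinct sequences identical over the
#' retained columns; duplicates are merged and their counts added.
#'
#' @param trimmed the `trimmed` element of [trim_blunt()].
#' @return An `aligned_seqs` data.frame with distinct `gapped` strings,
#'   sorted by decreasing total count (ties lexicographic).
#' @export
merge_trimmed_duplicates <- function(trimmed) {
  if (nrow(trimmed) == 0) return(trimmed)
  grp <- split(seq_len(nrow(trimmed)), trimmed$gapped)
  cols <- sample_count_cols(trimmed)
  rows <- lapply(grp, function(i) {
    r <- trimmed[i[1], , drop = FALSE]
    if (length(i) > 1) {
      r$total_count <- sum(trimmed$total_count[i])
      for (cn in cols) r[[cn]] <- sum(trimmed[[cn]][i])
    }
    r
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$total_count, out$gapped), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a unique-sequence table as FASTA plus count TSV
#'
#' @param uniques a `unique_seqs`/`aligned_seqs` data.frame.
#' @param fasta_file,count_file output paths; either may be `NULL`.
#' @param use_gapped write the aligned (gapped) sequences when available.
#' @export
write_unique_seqs <- function(uniques, fasta_file = NULL, count_file = NULL,
                              use_gapped = FALSE) {
  if (!is.null(fasta_file)) {
    s <- if (use_gapped) uniques$gapped else uniques$sequence
    x <- Biostrings::BStringSet(s)
    names(x) <- uniques$seq_id
    Biostrings::writeXStringSet(x, fasta_file)
  }
  if (!is.null(count_file)) {
    df <- uniques[, c("seq_id", "total_count", sample_count_cols(uniques))]
    write.table(df, count_file, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(uniques)
}
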