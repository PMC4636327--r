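# Steps 2-3 of the analysis pipeline. MiSeq substitution errors (~0.1% per
# base) are rare and positionally random, so erroneous reads sit within a few
# differences of an abundant true sequence: an abundance-ranked single-linkage
# pre-clustering absorbs them, post-merge singletons are withdrawn, and PCR
# chimeras are screened de novo against the more abundant working set.

# Column-wise difference count between two aligned integer vectors:
# each mismatching column counts 1 (gap-vs-base included), gap-vs-gap 0.
col_diffs <- function(a, b) {
  sum(a != b & !(a == 0L & b == 0L))
}

#' Pre-cluster near-identical sequences by abundance rank
#'
#' Processes aligned unique sequences in decreasing abundance (ties by
#' lexicographic sequence). Each sequence is compared against all
#' more-abundant retained sequences and merged into the most abundant one
#' within `max_diffs` column differences (a gap aligned to a base counts one
#' difference; gap against gap none). Merging is single-pass: ranks are fixed
#' at the start and counts added to the absorber do not promote it.
#' Post-merge singletons are removed as uncaught sequencing errors or taxa
#' below the method's background.
#'
#' @param uniques an `aligned_seqs` data.frame whose `gapped` strings share
#'   one (blunt-trimmed) length.
#' @param max_diffs maximum differences allowed for a merge (default 3).
#' @param remove_singletons drop post-merge records with total count 1
#'   (default `TRUE`).
#' @return List with `merged` (the surviving `aligned_seqs`), `merge_map`
#'   (named character: absorbed seq_id -> absorbing seq_id),
#'   `singletons_removed`, and `reads_in`/`reads_out` totals.
#' @export
precluster <- function(uniques, max_diffs = 3L, remove_singletons = TRUE) {
  n <- nrow(uniques)
  reads_in <- sum(uniques$total_count)
  if (n == 0) {
    return(list(merged = uniques, merge_map = character(0),
                singletons_removed = 0L, reads_in = 0L, reads_out = 0L))
  }
  if (length(unique(nchar(uniques$gapped))) > 1) {
    stop("precluster requires blunt-trimmed sequences of equal aligned length")
  }
  ord <- order(-uniques$total_count, uniques$gapped)
  u <- uniques[ord, , drop = FALSE]
  m <- seq_int_matrix(u$gapped)
  cols <- sample_count_cols(u)
  absorbed_into <- rep(NA_integer_, n)   # row index of absorber (in rank order)
  retained <- 1L
  merge_map <- character(0)
  for (i in seq_len(n)[-1]) {
    rm_rows <- retained
    d <- rowSums(
      m[rm_rows, , drop = FALSE] != matrix(m[i, ], length(rm_rows),
                                           ncol(m), byrow = TRUE) &
        !(m[rm_rows, , drop = FALSE] == 0L &
            matrix(m[i, ], length(rm_rows), ncol(m), byrow = TRUE) == 0L))
    hit <- which(d <= max_diffs)
    if (length(hit)) {
      # retained rows are already in decreasing-abundance order
      tgt <- rm_rows[hit[1]]
      absorbed_into[i] <- tgt
      merge_map[u$seq_id[i]] <- u$seq_id[tgt]
    } else {
      retained <- c(retained, i)
    }
  }
  # add absorbed counts to absorbers
  for (i in which(!is.na(absorbed_into))) {
    tgt <- absorbed_into[i]
    u$total_count[tgt] <- u$total_count[tgt] + u$total_count[i]
    for (cn in cols) u[[cn]][tgt] <- u[[cn]][tgt] + u[[cn]][i]
  }
  out <- u[retained, , drop = FALSE]
  singles <- out$total_count == 1L
  singletons_removed <- sum(singles)
  if (remove_singletons) out <- out[!singles, , drop = FALSE]
  out <- out[order(-out$total_count, out$gapped), , drop = FALSE]
  rownames(out) <- NULL
  list(merged = out, merge_map = merge_map,
       singletons_removed = as.integer(singletons_removed),
       reads_in = reads_in, reads_out = sum(out$total_count))
}

# Prefix cumulative mismatch profiles of query vs every parent, used to
# evaluate all single-crossover two-parent models in O(parents * columns).
chimera_model_search <- function(qv, parent_mat) {
  np <- nrow(parent_mat)
  nc <- ncol(parent_mat)
  mism <- parent_mat != matrix(qv, np, nc, byrow = TRUE) &
    !(parent_mat == 0L & matrix(qv, np, nc, byrow = TRUE) == 0L)
  cum <- t(apply(mism, 1, cumsum))            # parents x columns
  if (np == 1) cum <- matrix(cum, nrow = 1)
  total <- cum[, nc]
  best_single <- which.min(total)
  # for each crossover c (left = 1..c, right = c+1..nc):
  # best left parent mismatches + best right parent mismatches
  left_best <- apply(cum[, -nc, drop = FALSE], 2, min)
  right_best <- apply(sweep(-cum[, -nc, drop = FALSE], 1, total, `+`), 2, min)
  model <- left_best + right_best
  c_best <- which.min(model)
  la <- which.min(cum[, c_best])
  rb <- which.min(total - cum[, c_best])
  list(best_single = best_single, single_mism = total[best_single],
       crossover = c_best,
       left_parent = la, right_parent = rb,
       model_mism = model[c_best],
       mism = mism, total = total)
}

#' Screen chimeras de novo against the abundant working set
#'
#' Queries are processed in increasing abundance; candidate parents are
#' non-flagged sequences whose abundance is at least `skew` times the query's.
#' The query is split into `chunks` column blocks to shortlist candidate
#' parents (the best-matching parent per block plus the best overall), then
#' the best two-parent model with a single crossover is found by exhaustive
#' search over all column boundaries. When that model explains strictly more
#' columns than the best single parent, the score
#' `Y / (Y + beta * N + eps)` is computed, with `Y` the columns where the
#' query matches the model but not the single parent, and `N` the reverse.
#' A query is called chimeric when the score reaches `score_threshold` and it
#' differs from each parent by at least `min_parent_diffs` columns; flagged
#' queries never serve as parents.
#'
#' A chimera's two parents are, by construction, near-copies of the query
#' over their respective segments, so only sequences within
#' `1 - min_parent_identity` column divergence of the query are eligible as
#' parents; without this floor, two unrelated abundant sequences can
#' spuriously "explain" a divergent query better than either alone.
#'
#' @param uniques an `aligned_seqs` data.frame (blunt, equal lengths).
#' @param chunks number of column blocks for parent shortlisting (default 4).
#' @param skew minimum parent/query abundance ratio (default 2).
#' @param score_threshold minimum chimera score (default 0.28).
#' @param beta,eps score penalty weight and damping (defaults 8, 0.5).
#' @param min_parent_diffs minimum differences to each parent (default 3).
#' @param min_parent_identity minimum column identity between the query and
#'   any candidate parent (default 0.8).
#' @param min_div minimum improvement of the two-parent model over the best
#'   single parent, as a fraction of aligned columns (default 0.008). A
#'   one-column "improvement" arises by chance whenever a private
#'   substitution near a sequence end coincides with another parent's base,
#'   so sub-threshold models are not treated as chimeric evidence.
#' @param max_model_mismatch_frac maximum fraction of columns the two-parent
#'   model may leave unexplained (default 0.01). A genuine chimera is a
#'   concatenation of two sequences that are present in the working set, so
#'   its model residual is on the sequencing-error scale; a "model" that
#'   still mismatches many columns is a coincidental improvement between
#'   unrelated sequences, not chimeric structure.
#' @return data.frame with `query_id`, `parent_a`, `parent_b`, `score`,
#'   `is_chimera`.
#' @export
screen_chimeras <- function(uniques, chunks = 4L, skew = 2.0,
                            score_threshold = 0.28, beta = 8, eps = 0.5,
                            min_parent_diffs = 3L, min_parent_identity = 0.8,
                            min_div = 0.008, max_model_mismatch_frac = 0.01) {
  n <- nrow(uniques)
  verdicts <- data.frame(query_id = character(n), parent_a = NA_character_,
                         parent_b = NA_character_, score = NA_real_,
                         is_chimera = FALSE)
  if (n == 0) return(verdicts)
  ord <- order(-uniques$total_count, uniques$gapped)   # decreasing abundance
  u <- uniques[ord, , drop = FALSE]
  m <- seq_int_matrix(u$gapped)
  nc <- ncol(m)
  block <- pmin(ceiling(seq_len(nc) / (nc / chunks)), chunks)
  flagged <- logical(n)
  verdicts$query_id <- u$seq_id
  for (qi in rev(seq_len(n))) {                        # increasing abundance
    parents <- which(!flagged &
                       u$total_count >= skew * u$total_count[qi] &
                       seq_len(n) != qi)
    if (length(parents) < 2) next
    qv <- m[qi, ]
    pm <- m[parents, , drop = FALSE]
    mism <- pm != matrix(qv, length(parents), nc, byrow = TRUE) &
      !(pm == 0L & matrix(qv, length(parents), nc, byrow = TRUE) == 0L)
    total <- rowSums(mism)
    near <- total <= (1 - min_parent_identity) * nc
    if (sum(near) < 2) next
    parents <- parents[near]
    mism <- mism[near, , drop = FALSE]
    total <- total[near]
    pm <- pm[near, , drop = FALSE]
    # the crossover search is exhaustive over all eligible parents; the
    # chunk-based shortlist (best parents per block) only kicks in for
    # large parent pools, where it bounds the search like the cited tool's
    # chunked candidate nomination
    if (length(parents) <= 64L) {
      short <- seq_along(parents)
    } else {
      short <- unique(c(which.min(total),
                        unlist(lapply(seq_len(chunks), function(b) {
                          bm <- rowSums(mism[, block == b, drop = FALSE])
                          order(bm)[seq_len(min(8L, length(bm)))]
                        }))))
    }
    sm <- chimera_model_search(qv, pm[short, , drop = FALSE])
    if (sm$model_mism >= sm$single_mism) next
    if (sm$single_mism - sm$model_mism < max(1, ceiling(min_div * nc))) next
    if (sm$model_mism > max_model_mismatch_frac * nc) next
    la <- short[sm$left_parent]; rb <- short[sm$right_parent]
    cb <- sm$crossover
    single <- sm$mism[sm$best_single, ]
    model <- c(sm$mism[sm$left_parent, 1:cb],
               sm$mism[sm$right_parent, (cb + 1L):nc])
    Y <- sum(single & !model)
    N <- sum(!single & model)
    score <- Y / (Y + beta * N + eps)
    d_a <- sum(sm$mism[sm$left_parent, ])
    d_b <- sum(sm$mism[sm$right_parent, ])
    is_chim <- score >= score_threshold &&
      d_a >= min_parent_diffs && d_b >= min_parent_diffs
    verdicts$parent_a[qi] <- u$seq_id[parents[la]]
    verdicts$parent_b[qi] <- u$seq_id[parents[rb]]
    verdicts$score[qi] <- score
    if (is_chim) {
      verdicts$is_chimera[qi] <- TRUE
      flagged[qi] <- TRUE
    }
  }
  rownames(verdicts) <- NULL
  verdicts
}

#' Remove flagged chimeras from the working set
#'
#' @param uniques an `aligned_seqs` data.frame.
#' @param verdicts data.frame from [screen_chimeras()].
#' @return List with `kept`, `removed`, and read totals.
#' @export
apply_chimera_verdicts <- function(uniques, verdicts) {
  bad_ids <- verdicts$query_id[verdicts$is_chimera]
  drop <- uniques$seq_id %in% bad_ids
  list(kept = `rownames<-`(uniques[!drop, , drop = FALSE], NULL),
       removed = `rownames<-`(uniques[drop, , drop = FALSE], NULL),
       reads_in = sum(uniques$total_count),
       reads_out = sum(uniques$total_count[!drop]))
}

#' Write a chimera report TSV
#'
#' @param verdicts data.frame from [screen_chimeras()].
#' @param file output path.
#' @export
write_chimera_report <- function(verdicts, file) {
  write.table(verdicts, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
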