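# Multiplex index design for single-index MiSeq runs.
#
# Two-stage algorithm: (1) exhaustive greedy generation of 6-mer candidates
# under pairwise distance and complementarity rules; (2) selection of a panel
# whose per-position base composition is close to 25% per base and whose
# A/C-vs-T/G channel balance (the two MiSeq excitation LEDs) is close to 50%
# at every position.

INDEX_LENGTH <- 6L

#' Hamming distance between two equal-length DNA strings
#'
#' @param a,b character scalars of equal length.
#' @return Non-negative integer count of differing positions.
#' @export
#' @examples
#' hamming_distance("AAAAAA", "AAAAAT")
hamming_distance <- function(a, b) {
  if (nchar(a) != nchar(b)) {
    stop("hamming_distance: sequences have unequal lengths (",
         nchar(a), " vs ", nchar(b), ")")
  }
  sum(utf8ToInt(toupper(a)) != utf8ToInt(toupper(b)))
}

validate_index <- function(x) {
  if (nchar(x) != INDEX_LENGTH || grepl("[^ACGT]", x)) {
    stop("multiplex index must be a 6-mer over {A,C,G,T}: ", x)
  }
  invisible(x)
}

#' Pairwise compatibility of two multiplex indexes
#'
#' Two indexes are compatible when they differ at two or more positions and
#' neither is the complement nor the reverse complement of the other, so that
#' single sequencing errors cannot cross-assign reads and index-hopping
#' artefacts on the complementary strand are excluded.
#'
#' @param a,b 6-mer index sequences.
#' @return Logical scalar.
#' @export
is_compatible_pair <- function(a, b) {
  validate_index(a); validate_index(b)
  a <- toupper(a); b <- toupper(b)
  hamming_distance(a, b) >= 2 &&
    b != dna_complement(a) &&
    b != dna_revcomp(a)
}

# All 4^6 hexamers in lexicographic order (A < C < G < T).
all_hexamers <- function() {
  g <- expand.grid(p6 = DNA_BASES, p5 = DNA_BASES, p4 = DNA_BASES,
                   p3 = DNA_BASES, p2 = DNA_BASES, p1 = DNA_BASES,
                   stringsAsFactors = FALSE)
  do.call(paste0, g[, 6:1])
}

#' Generate the greedy candidate pool of multiplex indexes
#'
#' Scans all 4096 hexamers in lexicographic order and accepts each one that is
#' compatible ([is_compatible_pair()]) with every previously accepted index.
#' The result is a deterministic, maximal greedy clique under the pairwise
#' rules; output order is acceptance (lexicographic) order.
#'
#' @return Character vector of accepted index sequences.
#' @export
generate_index_candidates <- function() {
  hex <- all_hexamers()
  m <- seq_int_matrix(hex)
  acc <- matrix(integer(0), nrow = 0, ncol = INDEX_LENGTH)
  keep <- logical(length(hex))
  # forbidden = complements and reverse complements of accepted indexes
  forbidden <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_along(hex)) {
    v <- m[i, ]
    if (nrow(acc)) {
      d <- rowSums(acc != matrix(v, nrow(acc), INDEX_LENGTH, byrow = TRUE))
      if (any(d < 2)) next
    }
    if (!is.null(forbidden[[hex[i]]])) next
    acc <- rbind(acc, v)
    keep[i] <- TRUE
    forbidden[[dna_complement(hex[i])]] <- TRUE
    forbidden[[dna_revcomp(hex[i])]] <- TRUE
  }
  hex[keep]
}

# 6 x 4 per-position base-count matrix for a set of indexes.
index_base_counts <- function(indexes) {
  m <- seq_int_matrix(indexes)
  t(vapply(seq_len(ncol(m)), function(p) tabulate(m[, p], nbins = 4L),
           integer(4)))
}

# Balance objective from a 6 x 4 count matrix:
# sum over positions of |A/C channel fraction - 0.5|
# plus sum of squared deviations of each base fraction from 0.25.
balance_objective_counts <- function(counts, n) {
  frac <- counts / n
  ac <- frac[, 1] + frac[, 2]
  sum(abs(ac - 0.5)) + sum((frac - 0.25)^2)
}

#' Balance objective of an index set
#'
#' Quantifies how far a panel's per-position composition is from ideal:
#' the A/C excitation-channel fraction should be 0.5 and every base fraction
#' 0.25 at each of the six positions. Lower is better; 0 is perfect.
#'
#' @param indexes character vector of 6-mer indexes.
#' @return Numeric scalar.
#' @export
balance_objective <- function(indexes) {
  balance_objective_counts(index_base_counts(indexes), length(indexes))
}

#' Select a color-balanced index panel
#'
#' Chooses `panel_size` indexes from a candidate pool, minimizing the
#' composition [balance_objective()] by deterministic greedy construction
#' followed by greedy swap refinement (best-improving swap first; ties broken
#' by the lexicographically smallest incoming index). All pairwise
#' compatibility constraints are preserved on the output.
#'
#' @param candidates character vector of candidate indexes, e.g. from
#'   [generate_index_candidates()]. Candidates must be pairwise compatible or
#'   compatibility is enforced during selection.
#' @param panel_size number of indexes to select (default 320).
#' @param check_balance if `TRUE` (default), error when the selected panel's
#'   A/C channel fraction falls outside `0.5 +/- balance_tol` at any position.
#'   Disable for tiny panels where composition bands are meaningless.
#' @param balance_tol half-width of the acceptable channel-balance band
#'   (default 0.15).
#' @param max_passes maximum swap-refinement passes.
#' @return An object of class `index_panel`: list with `indexes`,
#'   `per_position_base_fraction` (6 x 4), `channel_balance` (length 6),
#'   and `objective`.
#' @export
select_index_panel <- function(candidates, panel_size = 320L,
                               check_balance = TRUE, balance_tol = 0.15,
                               max_passes = 50L) {
  candidates <- toupper(candidates)
  for (x in candidates) validate_index(x)
  if (anyDuplicated(candidates)) stop("duplicate candidate indexes")
  n <- length(candidates)
  if (panel_size < 1) stop("panel_size must be positive")

  cand_mat <- seq_int_matrix(candidates)
  # one-hot per candidate: 24 cells (6 positions x 4 bases)
  onehot <- matrix(0L, n, 24L)
  for (p in 1:6) {
    onehot[cbind(seq_len(n), (p - 1L) * 4L + cand_mat[, p])] <- 1L
  }

  compat <- function(i, j) { # indices into candidates
    a <- candidates[i]; b <- candidates[j]
    sum(cand_mat[i, ] != cand_mat[j, ]) >= 2 &&
      b != dna_complement(a) && b != dna_revcomp(a)
  }
  # candidate pools from generate_index_candidates() are cliques; detect once
  is_clique <- TRUE
  if (n > 1) {
    for (i in seq_len(n - 1L)) {
      d <- rowSums(cand_mat[(i + 1L):n, , drop = FALSE] !=
                     matrix(cand_mat[i, ], n - i, 6, byrow = TRUE))
      bad <- d < 2 |
        candidates[(i + 1L):n] == dna_complement(candidates[i]) |
        candidates[(i + 1L):n] == dna_revcomp(candidates[i])
      if (any(bad)) { is_clique <- FALSE; break }
    }
  }
  feasible_with <- function(j, members) {
    if (is_clique) return(TRUE)
    all(vapply(members, function(i) compat(i, j), logical(1)))
  }

  # greedy construction: repeatedly add the candidate minimizing the objective
  members <- integer(0)
  counts <- matrix(0L, 6, 4)
  for (step in seq_len(panel_size)) {
    avail <- setdiff(seq_len(n), members)
    avail <- avail[vapply(avail, feasible_with, logical(1), members = members)]
    if (!length(avail)) {
      stop("index panel of size ", panel_size, " is infeasible; ",
           "largest achievable size is ", length(members))
    }
    base <- as.vector(t(counts))
    trial <- matrix(base, length(avail), 24L, byrow = TRUE) +
      onehot[avail, , drop = FALSE]
    obj <- panel_objective_rows(trial, step)
    best <- avail[obj == min(obj)]
    pick <- best[order(candidates[best])][1]
    members <- c(members, pick)
    counts <- counts + matrix(onehot[pick, ], 6, 4, byrow = TRUE)
  }

  # swap refinement
  for (pass in seq_len(max_passes)) {
    improved <- FALSE
    cur_obj <- balance_objective_counts(counts, panel_size)
    best_gain <- 0; best_out <- NA_integer_; best_in <- NA_integer_
    outside <- setdiff(seq_len(n), members)
    if (!length(outside)) break
    for (m_i in members) {
      counts_minus <- as.vector(t(counts)) - onehot[m_i, ]
      others <- setdiff(members, m_i)
      ok <- outside[vapply(outside, feasible_with, logical(1), members = others)]
      if (!length(ok)) next
      trial <- matrix(counts_minus, length(ok), 24L, byrow = TRUE) +
        onehot[ok, , drop = FALSE]
      obj <- panel_objective_rows(trial, panel_size)
      gain <- cur_obj - obj
      g <- max(gain)
      if (g <= 1e-15) next
      # deterministic tie-break among equal gains: smallest incoming index
      tied <- which(gain >= g - 1e-15)
      jj <- tied[order(candidates[ok[tied]])][1]
      take <- g > best_gain + 1e-15 ||
        (abs(g - best_gain) <= 1e-15 && !is.na(best_in) &&
           candidates[ok[jj]] < candidates[best_in])
      if (take) {
        best_gain <- g; best_out <- m_i; best_in <- ok[jj]
      }
    }
    if (!is.na(best_in)) {
      counts <- counts +
        matrix(onehot[best_in, ] - onehot[best_out, ], 6, 4, byrow = TRUE)
      members <- c(setdiff(members, best_out), best_in)
      improved <- TRUE
    }
    if (!improved) break
  }

  sel <- candidates[sort(members)]
  frac <- index_base_counts(sel) / panel_size
  chan <- frac[, 1] + frac[, 2]
  if (check_balance && any(abs(chan - 0.5) > balance_tol + 1e-12)) {
    stop("selected panel violates the channel-balance band 0.5 +/- ",
         balance_tol, " (set check_balance = FALSE for tiny panels)")
  }
  structure(list(indexes = sel,
                 per_position_base_fraction = frac,
                 channel_balance = chan,
                 objective = balance_objective_counts(
                   index_base_counts(sel), panel_size)),
            class = "index_panel")
}

# objective for rows of 24-cell count vectors (positions x bases flattened)
panel_objective_rows <- function(trial, n) {
  frac <- trial / n
  ac <- frac[, c(1, 5, 9, 13, 17, 21), drop = FALSE] +
    frac[, c(2, 6, 10, 14, 18, 22), drop = FALSE]
  rowSums(abs(ac - 0.5)) + rowSums((frac - 0.25)^2)
}

#' @export
print.index_panel <- function(x, ...) {
  cat("Index panel:", length(x$indexes), "indexes\n")
  cat("Balance objective:", format(x$objective, digits = 4), "\n")
  cat("Channel balance (A/C fraction per position):",
      paste(format(x$channel_balance, digits = 3), collapse = " "), "\n")
  invisible(x)
}

#' Write an index panel and its composition QC to TSV
#'
#' @param panel an `index_panel`.
#' @param file panel output path (columns `index_id`, `sequence`).
#' @param qc_file optional QC output path with per-position base fractions.
#' @export
write_index_panel <- function(panel, file, qc_file = NULL) {
  df <- data.frame(index_id = sprintf("idx%03d", seq_along(panel$indexes)),
                   sequence = panel$indexes)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(qc_file)) {
    qc <- data.frame(position = 1:6, panel$per_position_base_fraction,
                     channel_AC = panel$channel_balance)
    names(qc)[2:5] <- DNA_BASES
    write.table(qc, qc_file, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(file)
}
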