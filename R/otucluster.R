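# Step 5: pairwise distances over the blunt-trimmed alignment, average
# neighbor (UPGMA-criterion) clustering at a 0.03 distance cutoff, consensus
# taxonomy per OTU at a 51% agreement cutoff, and the samples x OTUs table.

# Run-compressed pairwise distance between two aligned integer vectors:
# columns where both are gaps are skipped; a base-base mismatch counts one
# difference over one compared position; a maximal run of gap-vs-base
# columns counts one difference over one compared position.
dist_pair_int <- function(a, b) {
  keep <- !(a == 0L & b == 0L)
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (n == 0) return(0)
  gap <- (a == 0L) | (b == 0L)
  # collapse each maximal gap run to a single compared position
  run_start <- gap & !c(FALSE, gap[-n])
  diffs <- sum(a != b & !gap) + sum(run_start)
  compared <- sum(!gap) + sum(run_start)
  if (compared == 0) return(0)
  diffs / compared
}

#' Run-compressed distance between two aligned sequences
#'
#' Columns where both sequences are gapped are ignored; base-base mismatches
#' count one difference each, and a contiguous run of gap-against-base
#' columns counts a single difference (one indel event), following the usual
#' convention of distance-based OTU clustering.
#'
#' @param a,b gapped sequences of equal aligned length.
#' @return Distance in `[0, 1]`.
#' @export
pairwise_distance <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("aligned lengths differ")
  dist_pair_int(seq_to_int(toupper(a)), seq_to_int(toupper(b)))
}

#' All pairwise distances of a working set
#'
#' @param uniques an `aligned_seqs` data.frame (blunt, equal lengths), or a
#'   character vector of gapped sequences.
#' @param ids sequence ids (defaults to `seq_id` or names).
#' @return A symmetric matrix of class `dist_matrix` with zero diagonal.
#' @export
distance_matrix <- function(uniques, ids = NULL) {
  if (is.data.frame(uniques)) {
    seqs <- uniques$gapped %||% uniques$sequence
    ids <- ids %||% uniques$seq_id
  } else {
    seqs <- uniques
    ids <- ids %||% (names(uniques) %||% sprintf("s%03d", seq_along(uniques)))
  }
  n <- length(seqs)
  m <- seq_int_matrix(toupper(seqs))
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        d[i, j] <- d[j, i] <- dist_pair_int(m[i, ], m[j, ])
      }
    }
  }
  class(d) <- c("dist_matrix", "matrix")
  d
}

#' Average-neighbor OTU clustering
#'
#' Agglomerative clustering under the average-linkage (UPGMA) merge
#' criterion: the distance between two clusters is the mean distance over
#' all cross pairs of their member sequences. Merging proceeds while the
#' minimal inter-cluster average distance does not exceed `cutoff`.
#' Tie-breaking is deterministic: among equal minimal distances, the pair
#' whose (lexicographically sorted) cluster labels are smallest merges first,
#' a cluster's label being its lexicographically smallest member id.
#'
#' @param dm a `dist_matrix` (or plain symmetric matrix with dimnames).
#' @param cutoff maximum average distance for a merge (default 0.03). A value
#'   below 0.001 almost surely means "percent identity" was passed as a
#'   fraction of 1%; a warning is raised.
#' @param counts optional named read counts per sequence (used only to order
#'   and label the output OTUs by abundance).
#' @return List of OTUs, each a list with `otu_id`, `members`, `counts`,
#'   `total_count`, `representative_id`; ordered by decreasing total count.
#' @export
cluster_average_neighbor <- function(dm, cutoff = 0.03, counts = NULL) {
  ids <- rownames(dm)
  n <- length(ids)
  if (n == 0) return(list())
  if (cutoff < 0.001 && cutoff > 0) {
    warning("cutoff ", cutoff, " looks like a percent-identity fraction; ",
            "the conventional distance cutoff is 0.03")
  }
  counts <- counts %||% setNames(rep(1L, n), ids)
  active <- lapply(seq_len(n), function(i) i)   # member row indices
  labels <- ids
  d <- unclass(dm)
  size <- rep(1L, n)
  alive <- rep(TRUE, n)
  repeat {
    live <- which(alive)
    if (length(live) < 2) break
    # find minimal average distance among live clusters
    sub <- d[live, live, drop = FALSE]
    diag(sub) <- Inf
    mn <- min(sub)
    if (mn > cutoff) break
    hits <- which(sub <= mn + 1e-15, arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    # deterministic tie-break on sorted label pairs
    pair_lab <- apply(hits, 1, function(h) {
      paste(sort(c(labels[live[h[1]]], labels[live[h[2]]])), collapse = "\r")
    })
    h <- hits[order(pair_lab)[1], ]
    i <- live[h[1]]; j <- live[h[2]]
    # weighted average-linkage update
    for (kk in setdiff(live, c(i, j))) {
      d[i, kk] <- d[kk, i] <-
        (size[i] * d[i, kk] + size[j] * d[j, kk]) / (size[i] + size[j])
    }
    active[[i]] <- c(active[[i]], active[[j]])
    size[i] <- size[i] + size[j]
    labels[i] <- min(labels[i], labels[j])
    alive[j] <- FALSE
  }
  live <- which(alive)
  otus <- lapply(live, function(i) {
    mem <- ids[sort(active[[i]])]
    cts <- counts[mem]
    rep_id <- mem[order(-cts, mem)][1]
    list(members = mem, counts = cts, total_count = sum(cts),
         representative_id = rep_id)
  })
  ord <- order(-vapply(otus, `[[`, numeric(1), "total_count"),
               vapply(otus, `[[`, character(1), "representative_id"))
  otus <- otus[ord]
  for (k in seq_along(otus)) otus[[k]]$otu_id <- sprintf("OTU%04d", k)
  otus
}

#' Consensus taxonomy of an OTU
#'
#' Per rank, an abundance-weighted vote over the member assignments; the
#' winning label is kept only when its share reaches `cutoff` percent,
#' otherwise the rank and all deeper ranks are "unclassified".
#'
#' @param otu one OTU from [cluster_average_neighbor()].
#' @param assignments data.frame from [classify_uniques()].
#' @param cutoff agreement percentage (default 51).
#' @return Named character vector of per-rank labels, with attribute
#'   `agreement` (named numeric, percent of member reads behind each label).
#' @export
consensus_taxonomy <- function(otu, assignments, cutoff = 51) {
  i <- match(otu$members, assignments$seq_id)
  if (anyNA(i)) stop("assignments missing for OTU members")
  w <- as.numeric(otu$counts)
  labels <- setNames(rep("unclassified", length(TAX_RANKS)), TAX_RANKS)
  agree <- setNames(rep(NA_real_, length(TAX_RANKS)), TAX_RANKS)
  for (r in TAX_RANKS) {
    votes <- tapply(w, assignments[[r]][i], sum)
    share <- 100 * votes / sum(w)
    top <- names(share)[order(-share, names(share))][1]
    agree[r] <- share[top]
    if (top == "unclassified" || share[top] < cutoff) break
    labels[r] <- top
  }
  attr(labels, "agreement") <- agree
  labels
}

#' Build the samples x OTUs count table
#'
#' @param otus list from [cluster_average_neighbor()].
#' @param uniques the clustered `aligned_seqs` working set (provides
#'   per-sample counts).
#' @param assignments optional; when given, consensus lineages are attached.
#' @param consensus_cutoff agreement percentage for [consensus_taxonomy()].
#' @return An `otu_table`: list with `counts` (matrix samples x OTUs),
#'   `lineage` (matrix OTUs x ranks or `NULL`), `otus`.
#' @export
build_otu_table <- function(otus, uniques, assignments = NULL,
                            consensus_cutoff = 51) {
  scols <- sample_count_cols(uniques)
  if (!length(scols)) stop("uniques carry no per-sample counts")
  samples <- sub("^n\\.", "", scols)
  if (length(otus) == 0) {
    out <- list(counts = matrix(0L, length(samples), 0,
                                dimnames = list(samples, NULL)),
                lineage = NULL, otus = otus, empty = TRUE)
    class(out) <- "otu_table"
    return(out)
  }
  counts <- vapply(otus, function(o) {
    i <- match(o$members, uniques$seq_id)
    vapply(scols, function(cn) sum(uniques[[cn]][i]), numeric(1))
  }, numeric(length(scols)))
  if (length(scols) == 1) counts <- matrix(counts, nrow = 1)
  dimnames(counts) <- list(samples, vapply(otus, `[[`, character(1), "otu_id"))
  lineage <- NULL
  if (!is.null(assignments)) {
    lineage <- t(vapply(otus, function(o) {
      as.character(consensus_taxonomy(o, assignments, consensus_cutoff))
    }, character(length(TAX_RANKS))))
    dimnames(lineage) <- list(colnames(counts), TAX_RANKS)
  }
  out <- list(counts = counts, lineage = lineage, otus = otus, empty = FALSE)
  class(out) <- "otu_table"
  out
}

#' @export
print.otu_table <- function(x, ...) {
  cat("otu_table:", ncol(x$counts), "OTUs x", nrow(x$counts), "samples,",
      sum(x$counts), "reads\n")
  invisible(x)
}

#' Write an OTU table (rows = OTUs, sample columns, lineage last)
#'
#' @param table an `otu_table`.
#' @param file output TSV path.
#' @export
write_otu_table <- function(table, file) {
  if (isTRUE(table$empty)) {
    writeLines("# empty OTU table (no clustered sequences)", file)
    return(invisible(file))
  }
  df <- data.frame(otu_id = colnames(table$counts), t(table$counts))
  if (!is.null(table$lineage)) {
    df$lineage <- apply(table$lineage, 1, paste, collapse = ";")
  }
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write a distance matrix in square PHYLIP dialect
#'
#' @param dm a `dist_matrix`.
#' @param file output path.
#' @export
write_phylip_distances <- function(dm, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(dm)), con)
  for (i in seq_len(nrow(dm))) {
    writeLines(paste(c(rownames(dm)[i],
                       sprintf("%.6f", unclass(dm)[i, ])), collapse = "\t"),
               con)
  }
  invisible(file)
}
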