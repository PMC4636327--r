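# Diversity statistics: rarefaction curves by repeated subsampling,
# a neighbor-joining tree over OTU representatives, the generalized UniFrac
# distance with abundance-weight parameter alpha, principal coordinate
# analysis, and rank-level composition profiles with the "other (<0.5%)"
# and "unclassified" display categories.

#' Rarefaction curve for one sample
#'
#' For each depth on a grid of multiples of `step` (plus the full sample
#' total), the observed OTU richness is averaged over `resamples` random
#' subsamples drawn without replacement.
#'
#' @param counts named integer vector of per-OTU read counts.
#' @param step depth grid step (default 100).
#' @param resamples subsamples per depth (default 1000).
#' @param seed integer seed.
#' @return data.frame with `depth` and `mean_otus`.
#' @export
rarefaction_curve <- function(counts, step = 100L, resamples = 1000L,
                              seed = 1L) {
  counts <- counts[counts > 0]
  total <- sum(counts)
  if (total < step) stop("sample total below one rarefaction step")
  set.seed(seed)
  depths <- unique(c(seq(step, total, by = step), total))
  reads <- rep.int(seq_along(counts), counts)
  acc <- numeric(length(depths))
  # one permutation yields a valid without-replacement subsample at every
  # depth: richness at depth d = number of OTUs first seen within the first
  # d reads of the permutation
  for (b in seq_len(resamples)) {
    perm <- sample(reads)
    first_seen <- sort(match(seq_along(counts), perm))
    acc <- acc + findInterval(depths, first_seen)
  }
  data.frame(depth = depths, mean_otus = acc / resamples)
}

#' Closed-form expected rarefaction richness
#'
#' Hypergeometric expectation of the number of OTUs observed in a
#' without-replacement subsample of size `depth`:
#' `sum_i 1 - choose(total - n_i, depth) / choose(total, depth)`.
#'
#' @param counts per-OTU read counts.
#' @param depth subsample size.
#' @return Expected richness.
#' @export
expected_rarefaction <- function(counts, depth) {
  counts <- counts[counts > 0]
  total <- sum(counts)
  sum(1 - exp(lchoose(total - counts, depth) - lchoose(total, depth)))
}

#' Neighbor-joining tree over OTU representatives
#'
#' Builds the phylogeny used by the generalized UniFrac distance:
#' neighbor joining on the run-compressed pairwise distances of the OTU
#' representative sequences, midpoint-rooted, with negative branch lengths
#' clamped to zero.
#'
#' @param dm a `dist_matrix` over the representatives (leaf names = OTU ids),
#'   or an `aligned_seqs`-style data.frame of representatives.
#' @return An [ape::phylo] tree.
#' @export
build_representative_tree <- function(dm) {
  if (is.data.frame(dm)) dm <- distance_matrix(dm)
  n <- nrow(dm)
  if (n < 2) stop("tree building needs at least 2 representatives")
  if (n == 2) {
    d <- unclass(dm)[1, 2]
    tree <- ape::read.tree(
      text = sprintf("(%s:%f,%s:%f);", rownames(dm)[1], d / 2,
                     rownames(dm)[2], d / 2))
    return(tree)
  }
  tree <- ape::nj(stats::as.dist(unclass(dm)))
  tree <- phangorn::midpoint(tree)
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

# Per-edge subtree leaf-proportion sums via postorder accumulation.
edge_proportions <- function(tree, prop) {
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  acc <- numeric(n_tip + n_node)
  acc[seq_len(n_tip)] <- prop[tree$tip.label]
  edges <- tree$edge
  # postorder: children before parents
  for (e in ape::postorder(tree)) {
    acc[edges[e, 1]] <- acc[edges[e, 1]] + acc[edges[e, 2]]
  }
  acc[edges[, 2]]   # proportion below each edge
}

#' Generalized UniFrac distance between two community profiles
#'
#' With `p_i`, `q_i` the leaf-proportion sums below branch `i` and `b_i` the
#' branch length, the distance is
#' `sum_i b_i (p_i+q_i)^alpha |p_i-q_i|/(p_i+q_i) / sum_i b_i (p_i+q_i)^alpha`,
#' skipping branches with no support in either profile. `alpha` tunes the
#' weight of abundant lineages: 1 recovers the classic weighted-normalized
#' form, smaller values emphasize rarer lineages.
#'
#' @param tree an [ape::phylo] whose tip labels cover the profile names.
#' @param p,q named non-negative vectors over the tips, each summing to 1.
#' @param alpha abundance-weight exponent in `[0, 1]` (default 0.6, the
#'   preset used for dilution and negative-control comparisons; tissue
#'   ordinations conventionally use 0.2).
#' @return Distance in `[0, 1]`.
#' @export
generalized_unifrac <- function(tree, p, q, alpha = 0.6) {
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6) {
    stop("profiles must each sum to 1")
  }
  if (any(p < 0) || any(q < 0)) stop("profiles must be non-negative")
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  tips <- tree$tip.label
  pv <- setNames(rep(0, length(tips)), tips)
  qv <- pv
  pv[names(p)] <- p
  qv[names(q)] <- q
  bp <- edge_proportions(tree, pv)
  bq <- edge_proportions(tree, qv)
  b <- tree$edge.length
  s <- bp + bq
  keep <- s > 0 & b > 0
  if (!any(keep)) return(0)
  w <- b[keep] * s[keep]^alpha
  num <- sum(w * abs(bp[keep] - bq[keep]) / s[keep])
  den <- sum(w)
  if (den == 0) return(0)
  num / den
}

#' Generalized UniFrac distance matrix over samples
#'
#' @param tree an [ape::phylo] over the OTUs.
#' @param profiles matrix samples x OTUs of proportions (rows sum to 1).
#' @param alpha see [generalized_unifrac()].
#' @return A `dist_matrix` over samples.
#' @export
unifrac_matrix <- function(tree, profiles, alpha = 0.6) {
  n <- nrow(profiles)
  d <- matrix(0, n, n, dimnames = list(rownames(profiles), rownames(profiles)))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        d[i, j] <- d[j, i] <- generalized_unifrac(tree, profiles[i, ],
                                                  profiles[j, ], alpha)
      }
    }
  }
  class(d) <- c("dist_matrix", "matrix")
  d
}

#' Principal coordinate analysis
#'
#' Gower double-centering of `-0.5 * d^2`, eigendecomposition, and
#' coordinates scaled by the square roots of the positive eigenvalues.
#' Axes with negative eigenvalues are reported but carry no coordinates.
#' Per-axis sign is fixed by making the largest-magnitude loading positive.
#'
#' @param dm a `dist_matrix` (samples).
#' @return List with `coordinates` (samples x positive axes), `eigenvalues`
#'   (all), `variance_fraction` (per positive axis).
#' @export
pcoa_ordination <- function(dm) {
  d <- unclass(dm)
  n <- nrow(d)
  if (n < 2) stop("ordination needs at least 2 samples")
  a <- -0.5 * d^2
  jj <- diag(n) - matrix(1 / n, n, n)
  b <- jj %*% a %*% jj
  b <- (b + t(b)) / 2
  eg <- eigen(b, symmetric = TRUE)
  pos <- which(eg$values > 1e-9)
  coords <- eg$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(eg$values[pos]), length(pos))
  for (k in seq_len(ncol(coords))) {
    big <- which.max(abs(coords[, k]))
    if (coords[big, k] < 0) coords[, k] <- -coords[, k]
  }
  dimnames(coords) <- list(rownames(d),
                           sprintf("PCo%d", seq_len(ncol(coords))))
  list(coordinates = coords,
       eigenvalues = eg$values,
       variance_fraction = if (length(pos)) {
         eg$values[pos] / sum(eg$values[pos])
       } else numeric(0))
}

#' Rank-level composition profile with display categories
#'
#' Aggregates OTU counts to the labels of a taxonomic rank using the OTU
#' consensus lineages. OTUs unclassified at the rank feed the "unclassified"
#' category; taxa whose cross-sample mean proportion falls below
#' `other_threshold` are pooled into "other (<0.5%)". Per-sample proportions
#' sum to 1.
#'
#' @param table an `otu_table` with lineages.
#' @param rank one of `"domain"`, `"phylum"`, `"class"`, `"order"`,
#'   `"family"`, `"genus"`.
#' @param other_threshold mean-proportion pooling threshold (default 0.005).
#' @return Matrix samples x categories of proportions.
#' @export
composition_profile <- function(table, rank = "family",
                                other_threshold = 0.005) {
  if (!rank %in% TAX_RANKS) stop("unknown rank: ", rank)
  if (isTRUE(table$empty) || ncol(table$counts) == 0) {
    stop("empty OTU table has no composition")
  }
  if (is.null(table$lineage)) stop("OTU table carries no lineages")
  lab <- table$lineage[, rank]
  lab[lab == "unclassified"] <- "unclassified"
  counts <- table$counts
  agg <- t(rowsum(t(counts), lab))
  prop <- agg / rowSums(agg)
  means <- colMeans(prop)
  low <- names(means)[means < other_threshold & names(means) != "unclassified"]
  if (length(low)) {
    other <- rowSums(prop[, low, drop = FALSE])
    prop <- prop[, setdiff(colnames(prop), low), drop = FALSE]
    prop <- cbind(prop, `other (<0.5%)` = other)
  }
  ord <- c(setdiff(sort(colnames(prop)), c("other (<0.5%)", "unclassified")),
           intersect(c("other (<0.5%)", "unclassified"), colnames(prop)))
  prop[, ord, drop = FALSE]
}

#' Log10 display transform for profile tables
#'
#' `log10(proportion + eps)` with `eps` one tenth of the smallest nonzero
#' proportion, for heatmap-style table export of low-abundance taxa.
#'
#' @param profile matrix of proportions.
#' @return Matrix of the same shape.
#' @export
log10_profile <- function(profile) {
  nz <- profile[profile > 0]
  eps <- if (length(nz)) min(nz) / 10 else 1e-12
  log10(profile + eps)
}

#' Write ordination coordinates and eigenvalues
#'
#' @param ord result of [pcoa_ordination()].
#' @param coords_file,eigen_file output TSV paths (either may be `NULL`).
#' @export
write_ordination <- function(ord, coords_file = NULL, eigen_file = NULL) {
  if (!is.null(coords_file)) {
    write.table(data.frame(sample_id = rownames(ord$coordinates),
                           ord$coordinates),
                coords_file, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(eigen_file)) {
    write.table(data.frame(axis = seq_along(ord$eigenvalues),
                           eigenvalue = ord$eigenvalues),
                eigen_file, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(ord)
}
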