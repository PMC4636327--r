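# Validation metrics: deviation of a measured composition from the known
# mock design, variability between replicate profiles, and a generalized
# UniFrac check of whether a sample is dominated by the reagent background.

#' Deviation of a measured composition from the actual design
#'
#' Per-taxon absolute deviation in percentage points between a measured
#' profile and the known (actual) proportions, over the union of taxa
#' (missing taxa count as 0).
#'
#' @param measured named numeric vector or one row of a
#'   [composition_profile()] matrix (proportions).
#' @param actual named numeric vector of actual proportions.
#' @return A `deviation_report`: list with `per_taxon` (data.frame: `taxon`,
#'   `actual_pct`, `measured_pct`, `deviation_pct`) and `min`/`max`/`median`.
#' @export
composition_deviation <- function(measured, actual) {
  taxa <- union(names(measured), names(actual))
  m <- setNames(rep(0, length(taxa)), taxa)
  a <- m
  m[names(measured)] <- measured
  a[names(actual)] <- actual
  dev <- abs(m - a) * 100
  per_taxon <- data.frame(taxon = taxa, actual_pct = a * 100,
                          measured_pct = m * 100, deviation_pct = dev)
  rownames(per_taxon) <- NULL
  structure(list(per_taxon = per_taxon,
                 min = min(dev), max = max(dev), median = median(dev)),
            class = "deviation_report")
}

#' @export
print.deviation_report <- function(x, ...) {
  cat("composition deviation (percentage points): min",
      format(x$min, digits = 3), "max", format(x$max, digits = 3),
      "median", format(x$median, digits = 3), "\n")
  invisible(x)
}

#' Variability between replicate profiles
#'
#' Pools, per taxon, the absolute pairwise differences (in read percent)
#' across replicate profiles, and reports the overall median difference with
#' a bootstrap standard error of that median.
#'
#' @param profiles matrix replicates x taxa of proportions (>= 2 rows), or a
#'   list of named vectors over the same taxa.
#' @param bootstrap number of bootstrap resamples for the SEM (default 1000).
#' @param seed integer seed.
#' @return List with `per_taxon_median` (named, read percent),
#'   `median_difference`, `sem` and the pooled `differences`.
#' @export
replicate_variability <- function(profiles, bootstrap = 1000L, seed = 1L) {
  if (is.list(profiles) && !is.matrix(profiles)) {
    profiles <- do.call(rbind, profiles)
  }
  n <- nrow(profiles)
  if (is.null(n) || n < 2) stop("need at least 2 replicate profiles")
  prs <- utils::combn(n, 2)
  diffs <- abs(profiles[prs[1, ], , drop = FALSE] -
                 profiles[prs[2, ], , drop = FALSE]) * 100
  per_taxon <- apply(diffs, 2, median)
  pooled <- as.vector(diffs)
  set.seed(seed)
  boots <- vapply(seq_len(bootstrap), function(b) {
    median(sample(pooled, length(pooled), replace = TRUE))
  }, numeric(1))
  list(per_taxon_median = per_taxon,
       median_difference = median(pooled),
       sem = stats::sd(boots),
       differences = pooled)
}

#' Background-domination check against negative controls
#'
#' Computes the generalized UniFrac distance from a sample profile to each
#' negative-control profile on a shared OTU tree; the sample is flagged as
#' background-dominated when the distance to the nearest control falls below
#' `threshold`, mirroring how diluted samples converge to the water-control
#' profile on ordination plots.
#'
#' @param sample_profile named proportions over the tree tips.
#' @param control_profiles matrix controls x tips (or one named vector).
#' @param tree [ape::phylo] over the OTUs.
#' @param alpha UniFrac weight (default 0.6).
#' @param threshold flagging distance (default 0.2).
#' @return List with `distance` (to the nearest control), `flag`,
#'   `distances` (to all controls).
#' @export
background_check <- function(sample_profile, control_profiles, tree,
                             alpha = 0.6, threshold = 0.2) {
  if (is.null(control_profiles) ||
      (is.matrix(control_profiles) && nrow(control_profiles) == 0)) {
    stop("no negative-control profiles supplied")
  }
  if (!is.matrix(control_profiles)) {
    control_profiles <- matrix(control_profiles, nrow = 1,
                               dimnames = list("control1",
                                               names(control_profiles)))
  }
  ds <- vapply(seq_len(nrow(control_profiles)), function(i) {
    generalized_unifrac(tree, sample_profile, control_profiles[i, ], alpha)
  }, numeric(1))
  names(ds) <- rownames(control_profiles)
  list(distance = min(ds), flag = min(ds) < threshold, distances = ds)
}
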