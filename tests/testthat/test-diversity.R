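# Rarefaction, representative trees, generalized UniFrac, PCoA,
# composition profiles.

test_that("rarefaction at full depth equals observed richness", {
  counts <- c(o1 = 120, o2 = 60, o3 = 20)
  rc <- rarefaction_curve(counts, step = 100, resamples = 50, seed = 1)
  expect_equal(rc$mean_otus[rc$depth == 200], 3)
  expect_equal(max(rc$depth), 200)
  # a single-OTU sample stays constant at 1
  rc1 <- rarefaction_curve(c(only = 400), step = 100, resamples = 20, seed = 2)
  expect_true(all(rc1$mean_otus == 1))
  # curves never decrease
  expect_true(all(diff(rc$mean_otus) >= 0))
})

test_that("rarefaction means match the hypergeometric closed form", {
  counts <- c(50, 30, 10, 7, 3)
  depth <- 10
  rc <- rarefaction_curve(counts, step = 10, resamples = 1000, seed = 3)
  got <- rc$mean_otus[rc$depth == depth]
  # closed-form expectation and its standard error envelope
  expected <- expected_rarefaction(counts, depth)
  total <- sum(counts)
  p_seen <- 1 - exp(lchoose(total - counts, depth) - lchoose(total, depth))
  se <- sqrt(sum(p_seen * (1 - p_seen)) / 1000)
  expect_lt(abs(got - expected), 3 * max(se, 1e-3))
  # vegan's analytic rarefy agrees with our closed form
  expect_equal(expected,
               unname(suppressWarnings(
                 vegan::rarefy(matrix(counts, 1), depth))[1]),
               tolerance = 1e-9)
})

test_that("two-leaf trees get midpoint branches", {
  dm <- matrix(c(0, 0.1, 0.1, 0), 2, 2,
               dimnames = list(c("A", "B"), c("A", "B")))
  class(dm) <- c("dist_matrix", "matrix")
  tr <- build_representative_tree(dm)
  expect_setequal(tr$tip.label, c("A", "B"))
  expect_equal(sort(tr$edge.length), c(0.05, 0.05))
})

test_that("neighbor joining recovers an additive four-leaf metric", {
  # additive tree: ((A:2,B:3):1,(C:2,D:4))
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- d["B", "A"] <- 5
  d["A", "C"] <- d["C", "A"] <- 5
  d["A", "D"] <- d["D", "A"] <- 7
  d["B", "C"] <- d["C", "B"] <- 6
  d["B", "D"] <- d["D", "B"] <- 8
  d["C", "D"] <- d["D", "C"] <- 6
  d <- d / 10
  class(d) <- c("dist_matrix", "matrix")
  tr <- build_representative_tree(d)
  expect_true(all(tr$edge.length >= 0))
  # tree distances reproduce the additive input
  cd <- ape::cophenetic.phylo(tr)[LETTERS[1:4], LETTERS[1:4]]
  expect_equal(cd, unclass(d), tolerance = 1e-9, ignore_attr = TRUE)
})

# independent per-branch summation using clade tip sets from prop.part
gunifrac_oracle <- function(tree, p, q, alpha) {
  tips <- tree$tip.label
  num <- 0; den <- 0
  for (e in seq_len(nrow(tree$edge))) {
    node <- tree$edge[e, 2]
    below <- if (node <= length(tips)) {
      tips[node]
    } else {
      tips[unlist(ape::prop.part(tree)[[node - length(tips)]])]
    }
    pi <- sum(p[below]); qi <- sum(q[below])
    s <- pi + qi
    if (s == 0) next
    b <- tree$edge.length[e]
    num <- num + b * s^alpha * abs(pi - qi) / s
    den <- den + b * s^alpha
  }
  if (den == 0) 0 else num / den
}

random_profile <- function(tips) {
  x <- rexp(length(tips))
  setNames(x / sum(x), tips)
}

test_that("generalized UniFrac basics: identity, disjoint support", {
  tr <- ape::read.tree(text = "(A:1,B:1);")
  p <- c(A = 1, B = 0); q <- c(A = 0, B = 1)
  for (alpha in c(0, 0.3, 0.6, 1)) {
    expect_equal(generalized_unifrac(tr, p, p, alpha), 0)
    expect_equal(generalized_unifrac(tr, p, q, alpha), 1)
  }
  expect_error(generalized_unifrac(tr, c(A = 2, B = 0), q, 0.5), "sum to 1")
})

test_that("generalized UniFrac matches the traversal oracle", {
  set.seed(101)
  for (rep in 1:30) {
    tr <- ape::rtree(8)
    tr$tip.label <- sprintf("OTU%02d", 1:8)
    p <- random_profile(tr$tip.label)
    q <- random_profile(tr$tip.label)
    got <- generalized_unifrac(tr, p, q, 0.6)
    expect_equal(got, gunifrac_oracle(tr, p, q, 0.6), tolerance = 1e-12)
    expect_equal(got, generalized_unifrac(tr, q, p, 0.6), tolerance = 1e-12)
    expect_gte(got, 0); expect_lte(got, 1)
    # alpha = 1 equals the classic weighted-normalized formulation
    expect_equal(generalized_unifrac(tr, p, q, 1),
                 gunifrac_oracle(tr, p, q, 1), tolerance = 1e-12)
  }
})

test_that("PCoA reproduces Euclidean-embeddable configurations", {
  set.seed(102)
  pts <- matrix(rnorm(10), 5, 2)
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(paste0("s", 1:5), paste0("s", 1:5))
  ord <- pcoa_ordination(d)
  rec <- as.matrix(dist(ord$coordinates))
  expect_equal(unname(rec), unname(d), tolerance = 1e-9)
  expect_true(all(diff(ord$eigenvalues) <= 1e-9))  # descending
  # three equidistant samples: two equal eigenvalues, unit recovered distances
  d3 <- matrix(1, 3, 3); diag(d3) <- 0
  dimnames(d3) <- list(letters[1:3], letters[1:3])
  ord3 <- pcoa_ordination(d3)
  expect_equal(ord3$eigenvalues[1], ord3$eigenvalues[2], tolerance = 1e-9)
  rec3 <- as.matrix(dist(ord3$coordinates))
  expect_equal(unname(rec3), unname(d3), tolerance = 1e-9)
  # all-zero distances: no positive eigenvalues, zero coordinates
  d0 <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  ord0 <- pcoa_ordination(d0)
  expect_identical(ncol(ord0$coordinates), 0L)
  expect_true(all(abs(ord0$eigenvalues) < 1e-9))
})

test_that("PCoA agrees with classical scaling as an independent oracle", {
  set.seed(103)
  pts <- matrix(rnorm(12), 6, 2)
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(paste0("s", 1:6), paste0("s", 1:6))
  ord <- pcoa_ordination(d)
  cs <- stats::cmdscale(d, k = 2)
  for (k in 1:2) {
    expect_equal(abs(ord$coordinates[, k]), abs(cs[, k]), tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("composition profiles apply the other/unclassified conventions", {
  counts <- matrix(c(700, 290, 6, 4,
                     650, 340, 5, 5), 2, 4, byrow = TRUE,
                   dimnames = list(c("s1", "s2"),
                                   c("OTU1", "OTU2", "OTU3", "OTU4")))
  lineage <- matrix("x", 4, 6,
                    dimnames = list(colnames(counts),
                                    c("domain", "phylum", "class", "order",
                                      "family", "genus")))
  lineage[, "family"] <- c("F1", "F2", "F3", "unclassified")
  tab <- list(counts = counts, lineage = lineage, otus = NULL, empty = FALSE)
  class(tab) <- "otu_table"
  prof <- composition_profile(tab, "family")
  expect_equal(unname(rowSums(prof)), c(1, 1), tolerance = 1e-9)
  # F3 mean proportion is 0.55%, above the threshold, so it stays named
  expect_true("F3" %in% colnames(prof))
  counts2 <- counts; counts2[, 3] <- c(3, 2)
  tab2 <- tab; tab2$counts <- counts2
  prof2 <- composition_profile(tab2, "family")
  expect_true("other (<0.5%)" %in% colnames(prof2))
  expect_true("unclassified" %in% colnames(prof2))
  expect_false("F3" %in% colnames(prof2))
  # single-taxon table: that taxon at 1.0
  tab1 <- tab; tab1$counts <- counts[, 1, drop = FALSE]
  tab1$lineage <- lineage[1, , drop = FALSE]
  prof1 <- composition_profile(tab1, "family")
  expect_identical(colnames(prof1), "F1")
  expect_equal(unname(prof1[, 1]), c(1, 1))
  expect_error(composition_profile(tab, "species"), "unknown rank")
})
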