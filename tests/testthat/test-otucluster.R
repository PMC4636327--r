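# Pairwise distances, average-neighbor clustering, consensus taxonomy,
# OTU table construction.

# independent column-walk oracle for the run-compressed distance
dist_oracle <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  gapc <- c("-", ".")
  diffs <- 0; compared <- 0; in_gap_run <- FALSE
  for (i in seq_along(av)) {
    ga <- av[i] %in% gapc; gb <- bv[i] %in% gapc
    if (ga && gb) next              # shared gap: ignored, run continues? no -
    if (ga || gb) {
      if (!in_gap_run) {
        diffs <- diffs + 1
        compared <- compared + 1
        in_gap_run <- TRUE
      }
    } else {
      in_gap_run <- FALSE
      compared <- compared + 1
      if (av[i] != bv[i]) diffs <- diffs + 1
    }
  }
  if (compared == 0) 0 else diffs / compared
}

test_that("pairwise distance follows the run-compressed rule", {
  expect_equal(pairwise_distance("ACGTACGT", "ACGTACGT"), 0)
  s <- strrep("ACGT", 25)
  expect_equal(pairwise_distance(s, substitute_at(s, 7)), 0.01)
  # 3-column gap run + 2 substitutions over 100 columns:
  # compared = 97 bases + 1 gap event = 98; diffs = 3
  a <- strrep("ACGT", 25)
  b <- substitute_at(a, c(50, 60))
  b <- paste0(substr(b, 1, 9), "---", substr(b, 13, 100))
  expect_equal(pairwise_distance(a, b), dist_oracle(a, b))
  expect_equal(pairwise_distance(a, b), 3 / 98)
  expect_error(pairwise_distance("AC", "ACG"), "lengths differ")
})

test_that("distances match the column-walk oracle on random gapped pairs", {
  set.seed(91)
  for (rep in 1:60) {
    len <- sample(20:60, 1)
    mk <- function() {
      v <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
      ng <- sample(0:6, 1)
      if (ng > 0) v[sample(len, ng)] <- "-"
      paste(v, collapse = "")
    }
    a <- mk(); b <- mk()
    expect_equal(pairwise_distance(a, b), dist_oracle(a, b))
    expect_equal(pairwise_distance(a, b), pairwise_distance(b, a))
  }
})

# brute-force average-linkage oracle: recompute all cross-pair means at
# every step from the original matrix
avg_linkage_oracle <- function(d, cutoff) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  repeat {
    if (length(clusters) < 2) break
    best <- Inf; bi <- bj <- NA
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        avg <- mean(d[clusters[[i]], clusters[[j]]])
        lab <- paste(sort(c(min(rownames(d)[clusters[[i]]]),
                            min(rownames(d)[clusters[[j]]]))),
                     collapse = "\r")
        if (avg < best - 1e-15 ||
            (abs(avg - best) <= 1e-15 && !is.na(bi) &&
             lab < paste(sort(c(min(rownames(d)[clusters[[bi]]]),
                                min(rownames(d)[clusters[[bj]]]))),
                         collapse = "\r"))) {
          best <- avg; bi <- i; bj <- j
        }
      }
    }
    if (best > cutoff) break
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  partition <- lapply(clusters, function(ix) sort(rownames(d)[ix]))
  partition[order(vapply(partition, `[`, character(1), 1))]
}

partition_of <- function(otus) {
  p <- lapply(otus, function(o) sort(o$members))
  p[order(vapply(p, `[`, character(1), 1))]
}

test_that("simple hand-checked clusterings come out right", {
  d <- matrix(c(0, .01, .05,
                .01, 0, .05,
                .05, .05, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  otus <- cluster_average_neighbor(d, cutoff = 0.03)
  expect_identical(partition_of(otus), list(c("A", "B"), "C"))
  # all distances above cutoff: one OTU per sequence
  d2 <- matrix(0.5, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(d2) <- 0
  expect_length(cluster_average_neighbor(d2, 0.03), 4L)
})

test_that("clustering equals the brute-force oracle on random instances", {
  set.seed(92)
  for (rep in 1:60) {
    n <- sample(5:18, 1)
    pts <- matrix(runif(n * 2), n)
    d <- as.matrix(dist(pts)) / 4
    dimnames(d) <- list(sprintf("s%02d", 1:n), sprintf("s%02d", 1:n))
    cutoff <- runif(1, 0.05, 0.3)
    got <- partition_of(cluster_average_neighbor(d, cutoff))
    want <- avg_linkage_oracle(d, cutoff)
    expect_identical(got, want)
  }
})

test_that("partitions refine as the cutoff decreases", {
  set.seed(93)
  n <- 15
  d <- as.matrix(dist(matrix(runif(n * 2), n))) / 3
  dimnames(d) <- list(sprintf("s%02d", 1:n), sprintf("s%02d", 1:n))
  cuts <- c(0.02, 0.05, 0.1, 0.2)
  parts <- lapply(cuts, function(ct) {
    partition_of(cluster_average_neighbor(d, ct))
  })
  for (k in seq_len(length(cuts) - 1)) {
    fine <- parts[[k]]; coarse <- parts[[k + 1]]
    for (cl in fine) {
      host <- vapply(coarse, function(cc) all(cl %in% cc), logical(1))
      expect_identical(sum(host), 1L)
    }
  }
})

test_that("consensus taxonomy applies the 51% abundance-weighted vote", {
  asg <- data.frame(seq_id = c("a", "b"),
                    domain = "Bacteria", domain_conf = 100,
                    phylum = "P", phylum_conf = 100,
                    class = "C", class_conf = 100,
                    order = "O", order_conf = 100,
                    family = "F", family_conf = 100,
                    genus = c("X", "Y"), genus_conf = 100)
  otu64 <- list(members = c("a", "b"), counts = c(a = 6, b = 4),
                total_count = 10, representative_id = "a")
  cons <- consensus_taxonomy(otu64, asg)
  expect_identical(unname(cons["genus"]), "X")      # 60% >= 51%
  otu55 <- list(members = c("a", "b"), counts = c(a = 5, b = 5),
                total_count = 10, representative_id = "a")
  cons2 <- consensus_taxonomy(otu55, asg)
  expect_identical(unname(cons2["genus"]), "unclassified")  # 50% < 51%
  expect_identical(unname(cons2["family"]), "F")
  # agreement only at family: mixed deeper ranks stay unclassified
  asg3 <- asg
  asg3$genus <- c("X", "Y")
  otu37 <- list(members = c("a", "b"), counts = c(a = 3, b = 7),
                total_count = 10, representative_id = "b")
  cons3 <- consensus_taxonomy(otu37, asg3)
  expect_identical(unname(cons3["family"]), "F")
  expect_identical(unname(cons3["genus"]), "Y")     # 70% >= 51%
})

test_that("hierarchical consistency: a break propagates downward", {
  asg <- data.frame(seq_id = c("a", "b"),
                    domain = "Bacteria", domain_conf = 100,
                    phylum = c("P1", "P2"), phylum_conf = 100,
                    class = c("C1", "C1"), class_conf = 100,
                    order = "O", order_conf = 100,
                    family = "F", family_conf = 100,
                    genus = "G", genus_conf = 100)
  otu <- list(members = c("a", "b"), counts = c(a = 5, b = 5),
              total_count = 10, representative_id = "a")
  cons <- consensus_taxonomy(otu, asg)
  expect_identical(unname(cons["phylum"]), "unclassified")
  # class agrees among members but must stay unclassified below the break
  expect_identical(unname(cons["class"]), "unclassified")
})

test_that("OTU tables conserve per-sample counts", {
  set.seed(94)
  seqs <- rand_dna(4, 60)
  u <- make_uniques(seqs, c(10, 8, 5, 2))
  u$n.s1 <- c(6L, 4L, 3L, 1L)
  u$n.s2 <- c(4L, 4L, 2L, 1L)
  dm <- distance_matrix(u)
  otus <- cluster_average_neighbor(dm, 0.03,
                                   counts = setNames(u$total_count, u$seq_id))
  tab <- build_otu_table(otus, u)
  expect_identical(sum(tab$counts), 25)
  expect_identical(unname(rowSums(tab$counts)), c(14, 11))
  # single sample, single OTU
  u1 <- make_uniques(seqs[1], 7)
  t1 <- build_otu_table(cluster_average_neighbor(distance_matrix(u1), 0.03,
                                                 counts = c(u001 = 7)), u1)
  expect_identical(dim(t1$counts), c(1L, 1L))
  expect_identical(sum(t1$counts), 7)
  # empty working set gives the explicit empty marker
  t0 <- build_otu_table(list(), u1[0, ])
  expect_true(t0$empty)
})

test_that("representatives are the most abundant members", {
  set.seed(95)
  base <- rand_dna(1, 100)
  u <- make_uniques(c(base, substitute_at(base, 4)), c(3, 9))
  dm <- distance_matrix(u)
  otus <- cluster_average_neighbor(dm, 0.03,
                                   counts = setNames(u$total_count, u$seq_id))
  expect_length(otus, 1L)
  expect_identical(otus[[1]]$representative_id,
                   u$seq_id[u$total_count == 9])
})
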