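# Pre-clustering, singleton removal, and de novo chimera screening.

# independent pairwise difference counter (per-column; gap-gap free)
diff_oracle <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- 0L
  for (i in seq_along(av)) {
    ga <- av[i] %in% c("-", "."); gb <- bv[i] %in% c("-", ".")
    if (ga && gb) next
    if (av[i] != bv[i]) n <- n + 1L
  }
  n
}

# independent brute-force pre-clustering oracle following the stated rule:
# decreasing abundance, merge into most abundant retained within max_diffs
precluster_oracle <- function(seqs, counts, max_diffs = 3) {
  ord <- order(-counts, seqs)
  seqs <- seqs[ord]; counts <- counts[ord]
  owner <- seq_along(seqs)
  retained <- 1L
  for (i in seq_along(seqs)[-1]) {
    hit <- NA
    for (r in retained) {
      if (diff_oracle(seqs[i], seqs[r]) <= max_diffs) { hit <- r; break }
    }
    if (is.na(hit)) retained <- c(retained, i) else owner[i] <- hit
  }
  out_counts <- vapply(retained, function(r) sum(counts[owner == r]),
                       numeric(1))
  data.frame(sequence = seqs[retained], count = out_counts)
}

test_that("near-identical low-abundance sequences are absorbed", {
  set.seed(51)
  a <- rand_dna(1, 80)
  b <- substitute_at(a, c(10, 20))       # 2 diffs -> absorbed
  c2 <- substitute_at(a, c(5, 25, 45, 65))  # 4 diffs -> kept
  u <- make_uniques(c(a, b, c2), c(50, 3, 4))
  pc <- precluster(u)
  expect_identical(nrow(pc$merged), 2L)
  expect_identical(pc$merged$total_count[pc$merged$sequence == a], 53L)
  expect_identical(pc$merged$total_count[pc$merged$sequence == c2], 4L)
  expect_named(pc$merge_map, u$seq_id[u$sequence == b])
  expect_identical(pc$reads_in, 57L)
})

test_that("gap columns count per-column in precluster differences", {
  a <- "ACGTACGT"
  b <- "AC--ACGT"   # 2 gap columns vs bases = 2 diffs
  u <- make_uniques(c(a, b), c(10, 2))
  pc <- precluster(u, max_diffs = 2)
  expect_identical(nrow(pc$merged), 1L)
  expect_identical(pc$merged$total_count, 12L)
  pc1 <- precluster(u, max_diffs = 1)
  expect_identical(nrow(pc1$merged), 2L)
})

test_that("post-merge singletons are withdrawn and counted", {
  set.seed(52)
  a <- rand_dna(1, 60)
  lone <- rand_dna(1, 60)
  u <- make_uniques(c(a, lone), c(9, 1))
  pc <- precluster(u)
  expect_identical(pc$singletons_removed, 1L)
  expect_identical(nrow(pc$merged), 1L)
  expect_identical(pc$merged$sequence, a)
})

test_that("precluster matches the brute-force oracle on random instances", {
  set.seed(53)
  for (rep in 1:60) {
    n <- sample(4:12, 1)
    base <- rand_dna(1, 40)
    seqs <- unique(vapply(seq_len(n), function(i) {
      substitute_at(base, sample(40, sample(0:6, 1)))
    }, character(1)))
    counts <- sample(1:50, length(seqs), replace = TRUE)
    u <- make_uniques(seqs, counts)
    pc <- precluster(u, remove_singletons = FALSE)
    oracle <- precluster_oracle(seqs, counts)
    got <- pc$merged[order(pc$merged$sequence), ]
    want <- oracle[order(oracle$sequence), ]
    expect_identical(got$sequence, want$sequence)
    expect_identical(as.numeric(got$total_count), as.numeric(want$count))
    expect_identical(sum(pc$merged$total_count), sum(counts))  # conservation
  }
})

test_that("error-free reads from K templates precluster to exactly K", {
  setup <- make_mock_setup(5, seed = 54, depth = 3000, run_seed = 55,
                           substitution_rate = 0, indel_rate = 0)
  run <- simulate_run(setup$spec, setup$cfg)
  joined <- join_pairs(run$batch, join_config(kit = "v2"), "s1")$joined
  u <- dereplicate(joined)
  scr <- cull_nonspecific(u, setup$ref)
  blunt <- merge_trimmed_duplicates(trim_blunt(scr$kept)$trimmed)
  pc <- precluster(blunt)
  expect_identical(nrow(pc$merged), 5L)
  expect_identical(scr$culled_count, 0L)
})

test_that("deep noisy mock runs recover the template set exactly", {
  setup <- make_mock_setup(5, seed = 56, depth = 12000, run_seed = 57)
  run <- simulate_run(setup$spec, setup$cfg)
  joined <- join_pairs(run$batch, join_config(kit = "v2"), "s1")$joined
  u <- dereplicate(joined)
  scr <- cull_nonspecific(u, setup$ref)
  blunt <- merge_trimmed_duplicates(trim_blunt(scr$kept)$trimmed)
  pc <- precluster(blunt)
  pcr <- in_silico_pcr(setup$spec)
  templates <- substr(setup$spec$strains$sequence, pcr$start, pcr$end)
  expect_setequal(pc$merged$sequence, templates)
})

# exhaustive two-parent crossover oracle over all column boundaries,
# written independently of the implementation's prefix-sum search
chimera_oracle <- function(q, parents) {
  qv <- strsplit(q, "")[[1]]
  pv <- lapply(parents, function(p) strsplit(p, "")[[1]])
  nc <- length(qv)
  best_single <- Inf; best_single_i <- NA
  for (i in seq_along(pv)) {
    d <- sum(qv != pv[[i]])
    if (d < best_single) { best_single <- d; best_single_i <- i }
  }
  best_model <- Inf; best <- NULL
  for (a in seq_along(pv)) for (b in seq_along(pv)) {
    if (a == b) next
    for (cx in 1:(nc - 1)) {
      mm <- sum(qv[1:cx] != pv[[a]][1:cx]) +
        sum(qv[(cx + 1):nc] != pv[[b]][(cx + 1):nc])
      if (mm < best_model) {
        best_model <- mm
        best <- list(a = a, b = b, cx = cx)
      }
    }
  }
  list(single = best_single, single_i = best_single_i,
       model = best_model, parents = best)
}

test_that("a true two-parent mosaic is flagged with its parents", {
  set.seed(61)
  a <- rand_dna(1, 100)
  b <- substitute_at(a, sample(100, 10))        # 10% divergence
  q <- paste0(substr(a, 1, 50), substr(b, 51, 100))
  if (q %in% c(a, b)) skip("degenerate crossover draw")
  u <- make_uniques(c(a, b, q), c(100, 100, 5))
  v <- screen_chimeras(u)
  vq <- v[v$query_id == u$seq_id[u$sequence == q], ]
  expect_true(vq$is_chimera)
  ids <- u$seq_id[match(c(a, b), u$sequence)]
  expect_setequal(c(vq$parent_a, vq$parent_b), ids)
  # oracle agrees that a two-parent model beats any single parent
  or <- chimera_oracle(q, c(a, b))
  expect_lt(or$model, or$single)
})

test_that("a plain error variant is not called chimeric", {
  set.seed(62)
  a <- rand_dna(1, 100)
  b <- substitute_at(a, sample(100, 10))
  q <- substitute_at(a, c(3, 97))   # 2 errors, no mosaic structure
  u <- make_uniques(c(a, b, q), c(100, 100, 5))
  v <- screen_chimeras(u)
  expect_false(any(v$is_chimera))
})

test_that("the most abundant sequence has no eligible parents", {
  set.seed(63)
  seqs <- rand_dna(3, 80)
  u <- make_uniques(seqs, c(100, 40, 30))
  v <- screen_chimeras(u)
  expect_false(v$is_chimera[v$query_id == u$seq_id[1]])
})

test_that("crossover search matches the exhaustive all-boundary oracle", {
  # oracle over all ordered parent pairs (equal pair allowed, which reduces
  # to the single-parent model) and all column boundaries
  oracle_best <- function(q, parents) {
    qv <- strsplit(q, "")[[1]]
    pv <- lapply(parents, function(p) strsplit(p, "")[[1]])
    nc <- length(qv)
    single <- min(vapply(pv, function(p) sum(qv != p), numeric(1)))
    model <- Inf
    for (a in seq_along(pv)) for (b in seq_along(pv)) {
      for (cx in 1:(nc - 1)) {
        mm <- sum(qv[1:cx] != pv[[a]][1:cx]) +
          sum(qv[(cx + 1):nc] != pv[[b]][(cx + 1):nc])
        model <- min(model, mm)
      }
    }
    list(single = single, model = model)
  }
  set.seed(64)
  for (rep in 1:40) {
    np <- sample(2:5, 1)
    a <- rand_dna(1, 50)
    parents <- c(a, vapply(seq_len(np - 1), function(i) {
      substitute_at(a, sample(50, sample(5:12, 1)))
    }, character(1)))
    cx <- sample(5:45, 1)
    pick <- sample(np, 2)
    q <- substitute_at(
      paste0(substr(parents[pick[1]], 1, cx),
             substr(parents[pick[2]], cx + 1, 50)),
      sample(50, sample(0:2, 1)))
    sm <- tissamp16s:::chimera_model_search(
      tissamp16s:::seq_to_int(q),
      tissamp16s:::seq_int_matrix(parents))
    or <- oracle_best(q, parents)
    expect_identical(as.numeric(sm$single_mism), or$single)
    expect_identical(as.numeric(sm$model_mism), or$model)
  }
})

test_that("verdict application removes exactly the flagged records", {
  set.seed(65)
  u <- make_uniques(rand_dna(20, 50), sample(2:30, 20, replace = TRUE))
  v <- screen_chimeras(u)
  expect_false(any(v$is_chimera))        # random unrelated = no parents pass
  res <- apply_chimera_verdicts(u, v)
  expect_identical(nrow(res$kept), 20L)  # identity when nothing flagged
  v$is_chimera[match(u$seq_id[c(2, 5, 9)], v$query_id)] <- TRUE
  res2 <- apply_chimera_verdicts(u, v)
  expect_identical(nrow(res2$kept), 17L)
  expect_identical(res2$reads_in, res2$reads_out + sum(u$total_count[c(2, 5, 9)]))
})

test_that("injected chimeras are detected and clean runs stay unflagged", {
  setup <- make_mock_setup(14, seed = 1, depth = 20000, run_seed = 3,
                           primer_dropout = 8,
                           substitution_rate = 0, indel_rate = 0,
                           chimera_rate = 0.02)
  run <- simulate_run(setup$spec, setup$cfg)
  pcr <- in_silico_pcr(setup$spec)
  amp <- setup$amp
  templates <- substr(setup$spec$strains$sequence[amp],
                      pcr$start[amp], pcr$end[amp])
  joined <- join_pairs(run$batch, join_config(kit = "v2"), "s1")$joined
  u <- dereplicate(joined)
  scr <- cull_nonspecific(u, setup$ref)
  blunt <- merge_trimmed_duplicates(trim_blunt(scr$kept)$trimmed)
  work <- precluster(blunt)$merged
  truly_chimeric <- !(work$sequence %in% templates)
  expect_gt(sum(truly_chimeric), 10)
  v <- screen_chimeras(work)
  det <- v$is_chimera[match(work$seq_id, v$query_id)]
  expect_gte(sum(det & truly_chimeric) / sum(truly_chimeric), 0.9)
  expect_lte(sum(det & !truly_chimeric) / sum(!truly_chimeric), 0.01)
  # chimera-free run at default settings flags nothing
  setup2 <- make_mock_setup(6, seed = 66, depth = 8000, run_seed = 67)
  run2 <- simulate_run(setup2$spec, setup2$cfg)
  joined2 <- join_pairs(run2$batch, join_config(kit = "v2"), "s1")$joined
  blunt2 <- merge_trimmed_duplicates(
    trim_blunt(cull_nonspecific(dereplicate(joined2), setup2$ref)$kept)$trimmed)
  work2 <- precluster(blunt2)$merged
  v2 <- screen_chimeras(work2)
  expect_false(any(v2$is_chimera))
})
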