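# Mock-community read simulator. Emulates the validation designs used to
# qualify the pipeline: even mocks (10^7 16S copies per strain), staggered
# mocks (copies spanning 10^3-10^6), dilution series against a constant
# reagent-contaminant background, negative (water) controls, and MiSeq-like
# error injection (substitutions at 0.1% per base, indels negligible at
# 0.001%, optional PCR chimeras). Reads carry constant quality 38 with
# errored bases at 20, since the pipeline ignores quality priors by design.

MOCK_CORE_LEN <- 422L   # 467 bp region = fwd site (19) + core + rev site (26)

#' Synthesize a clade-structured mock community and matching references
#'
#' Generates `n_strains` 16S-like reference templates flanked by the
#' pipeline's primer-binding sites, with hierarchical divergence: family
#' ancestors carry 17 fixed substitutions from a shared root and each
#' strain 10 substitutions from its family ancestor, so strain pairs
#' diverge by ~4% within a family and ~11% across families. Strains listed in
#' `primer_dropout` receive 3 substitutions inside the forward primer site
#' and so cannot amplify. A disjoint classifier training set (per-strain
#' mutants at ~1% extra divergence) is emitted alongside.
#'
#' @param n_strains number of strains (>= 2).
#' @param seed integer seed.
#' @param primer_dropout integer indexes of strains whose forward primer
#'   site is disrupted.
#' @param copies per-strain 16S copy number: a scalar (even design; default
#'   1e7) or a vector of length `n_strains`.
#' @param design_name label: `"even"`, `"staggered"`, `"single"`, `"custom"`.
#' @param strains_per_family how many strains share a synthetic family
#'   (default 3).
#' @return A `mock_spec`: list with `strains` (data.frame: `name`, `lineage`,
#'   `sequence`, `copies`, `amplifiable`), `taxonomy` (a
#'   `taxonomy_reference` of training mutants), `design_name`.
#' @export
synth_reference_set <- function(n_strains, seed = 1L,
                                primer_dropout = integer(0),
                                copies = 1e7, design_name = "even",
                                strains_per_family = 3L) {
  if (n_strains < 2) stop("need at least 2 strains")
  set.seed(seed)
  root <- paste(sample(DNA_BASES, MOCK_CORE_LEN, replace = TRUE),
                collapse = "")
  n_fam <- ceiling(n_strains / strains_per_family)
  fam_anc <- vapply(seq_len(n_fam), function(f) mutate_positions(root, 17L),
                    character(1))
  fam_of <- rep(seq_len(n_fam), each = strains_per_family)[seq_len(n_strains)]
  cores <- vapply(seq_len(n_strains), function(s) {
    mutate_positions(fam_anc[fam_of[s]], 10L)
  }, character(1))
  fwd_site <- PRIMER_FWD
  rev_site <- dna_revcomp(PRIMER_REV)
  seqs <- paste0(fwd_site, cores, rev_site)
  # primer dropout: disrupt the forward site beyond the mismatch tolerance
  for (s in primer_dropout) {
    site <- mutate_positions(fwd_site, 3L)
    seqs[s] <- paste0(site, cores[s], rev_site)
  }
  names_ <- sprintf("Strain%02d", seq_len(n_strains))
  lineages <- sprintf(
    "Bacteria;Synthphylum%d;Synthclass%d;Synthorder%d;Synthfamily%d;Synthgenus%02d",
    fam_of, fam_of, fam_of, fam_of, seq_len(n_strains))
  if (length(copies) == 1) copies <- rep(copies, n_strains)
  strains <- data.frame(name = names_, lineage = lineages, sequence = seqs,
                        copies = copies,
                        amplifiable = !(seq_len(n_strains) %in% primer_dropout))
  # disjoint training mutants (~1% extra divergence over the full amplicon)
  train_seqs <- vapply(seqs, function(s) mutate_positions(s, 5L),
                       character(1), USE.NAMES = FALSE)
  taxonomy <- taxonomy_reference(paste0(names_, "_ref"), train_seqs, lineages)
  structure(list(strains = strains, taxonomy = taxonomy,
                 design_name = design_name),
            class = "mock_spec")
}

#' @export
print.mock_spec <- function(x, ...) {
  cat("mock_spec (", x$design_name, "): ", nrow(x$strains), " strains, ",
      sum(x$strains$amplifiable), " amplifiable\n", sep = "")
  invisible(x)
}

#' Synthetic reagent-contaminant background
#'
#' Five synthetic "reagent" strains with mutually distinct families,
#' emulating the bacterial DNA present in PCR reagents; generated from an
#' independent root so they are well separated from any mock community.
#'
#' @param seed integer seed.
#' @param n_strains number of contaminant strains (default 5).
#' @param copies_each 16S copies per contaminant (default 2e4).
#' @return A `mock_spec` with design `"background"`.
#' @export
synth_background <- function(seed = 99L, n_strains = 5L, copies_each = 2e4) {
  bg <- synth_reference_set(n_strains, seed = seed, copies = copies_each,
                            design_name = "background",
                            strains_per_family = 1L)
  bg$strains$name <- sprintf("Contam%02d", seq_len(n_strains))
  lin <- sprintf(
    "Bacteria;Contphylum%d;Contclass%d;Contorder%d;Contfamily%d;Contgenus%02d",
    seq_len(n_strains), seq_len(n_strains), seq_len(n_strains),
    seq_len(n_strains), seq_len(n_strains))
  bg$strains$lineage <- lin
  bg$taxonomy <- taxonomy_reference(paste0(bg$strains$name, "_ref"),
                                    bg$taxonomy$sequence, lin)
  bg
}

#' In silico PCR over a mock specification
#'
#' A strain amplifies when both primer sites are found with at most
#' `max_mismatches` each (the reverse primer is matched against the reverse
#' complement strand). The amplicon spans the forward site through the
#' reverse site.
#'
#' @param spec a `mock_spec`.
#' @param forward,reverse primer sequences (defaults: the pipeline's V3-V4
#'   primers).
#' @param max_mismatches per-site mismatch tolerance (default 2).
#' @return data.frame `name`, `amplifiable`, `start`, `end` (1-based
#'   amplicon interval; NA when not amplifiable).
#' @export
in_silico_pcr <- function(spec, forward = PRIMER_FWD, reverse = PRIMER_REV,
                          max_mismatches = 2L) {
  if (!nzchar(forward) || !nzchar(reverse)) stop("primers must be nonempty")
  rev_site <- dna_revcomp(reverse)
  res <- lapply(spec$strains$sequence, function(s) {
    f <- best_site_match(s, forward, max_mismatches)
    r <- best_site_match(s, rev_site, max_mismatches)
    if (is.na(f) || is.na(r) || r + nchar(rev_site) - 1 <= f) {
      return(c(NA_integer_, NA_integer_))
    }
    c(f, r + nchar(rev_site) - 1L)
  })
  m <- do.call(rbind, res)
  data.frame(name = spec$strains$name,
             amplifiable = !is.na(m[, 1]),
             start = m[, 1], end = m[, 2])
}

# First position where `site` matches a window of `s` with <= max_mm
# mismatches; NA when absent.
best_site_match <- function(s, site, max_mm) {
  sv <- utf8ToInt(s); tv <- utf8ToInt(site)
  L <- length(tv); n <- length(sv)
  if (n < L) return(NA_integer_)
  for (start in seq_len(n - L + 1L)) {
    if (sum(sv[start:(start + L - 1L)] != tv) <= max_mm) return(start)
  }
  NA_integer_
}

#' Simulation run configuration
#'
#' @param kit `"v2"` (2x250) or `"v3"` (2x300).
#' @param depth number of read pairs to emit.
#' @param substitution_rate per-base substitution probability (default 0.001,
#'   the MiSeq rate of 0.1%).
#' @param indel_rate per-base insertion/deletion probability (default 1e-5;
#'   MiSeq indels are negligible, <0.001%).
#' @param chimera_rate fraction of reads formed from two parents with one
#'   uniform crossover (default 0).
#' @param sample_id,index sample label and its 6-mer multiplex index.
#' @param seed integer seed.
#' @return A `seq_run_config` list.
#' @export
seq_run_config <- function(kit = "v2", depth = 10000L,
                           substitution_rate = 0.001, indel_rate = 1e-5,
                           chimera_rate = 0, sample_id = "sample1",
                           index = "ACACAC", seed = 1L) {
  kit <- match.arg(kit, c("v2", "v3"))
  stopifnot(depth >= 0, substitution_rate >= 0, substitution_rate <= 1,
            indel_rate >= 0, indel_rate <= 1,
            chimera_rate >= 0, chimera_rate <= 1)
  structure(list(kit = kit,
                 read_length = if (kit == "v2") 250L else 300L,
                 depth = as.integer(depth),
                 substitution_rate = substitution_rate,
                 indel_rate = indel_rate, chimera_rate = chimera_rate,
                 sample_id = sample_id, index = toupper(index),
                 seed = as.integer(seed)),
            class = "seq_run_config")
}

# Apply substitution/indel errors to one sequence; returns the sequence and
# the error positions (positions refer to the output string for qualities).
apply_errors <- function(s, sub_rate, indel_rate) {
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(v)
  n_err <- 0L
  errored <- logical(n)
  subs <- which(runif(n) < sub_rate)
  for (p in subs) {
    v[p] <- sample(setdiff(DNA_BASES, v[p]), 1)
    errored[p] <- TRUE
    n_err <- n_err + 1L
  }
  if (indel_rate > 0) {
    ind <- which(runif(n) < indel_rate)
    for (p in rev(ind)) {   # right-to-left keeps earlier positions valid
      if (runif(1) < 0.5) { # deletion
        v <- v[-p]; errored <- errored[-p]
      } else {              # insertion after p
        v <- append(v, sample(DNA_BASES, 1), after = p)
        errored <- append(errored, TRUE, after = p)
      }
      n_err <- n_err + 1L
    }
  }
  list(seq = paste(v, collapse = ""), errored = errored, n_errors = n_err)
}

#' Simulate a MiSeq sequencing run of a mock community
#'
#' Molecule proportions are the strain copies of amplifiable strains plus
#' any background copies; `depth` read pairs are drawn multinomially.
#' Each read takes its template amplicon, receives substitutions and indels
#' at the configured per-base rates, and is cut into two mates (mate 2
#' reverse-complemented) with constant quality 38 and errored bases at 20.
#' A `chimera_rate` fraction of reads is formed from two distinct parent
#' amplicons with a single uniform crossover and flagged in the truth table.
#'
#' @param spec a `mock_spec`.
#' @param cfg a [seq_run_config()].
#' @param background optional `mock_spec` of contaminants (copies used
#'   as given).
#' @param dir optional directory; when given, `r1.fastq.gz`, `r2.fastq.gz`
#'   are written there.
#' @return A list with `batch` (a `read_batch`), `truth` (data.frame:
#'   `read_id`, `template_id`, `sample_id`, `is_chimera`), and
#'   `expected_proportions` (named, amplifiable strains + background strains).
#' @export
simulate_run <- function(spec, cfg, background = NULL, dir = NULL) {
  set.seed(cfg$seed)
  pcr <- in_silico_pcr(spec)
  amp <- which(pcr$amplifiable & spec$strains$copies > 0)
  templates <- substr(spec$strains$sequence[amp], pcr$start[amp],
                      pcr$end[amp])
  tnames <- spec$strains$name[amp]
  copies <- spec$strains$copies[amp]
  if (!is.null(background)) {
    bpcr <- in_silico_pcr(background)
    bamp <- which(bpcr$amplifiable & background$strains$copies > 0)
    templates <- c(templates, substr(background$strains$sequence[bamp],
                                     bpcr$start[bamp], bpcr$end[bamp]))
    tnames <- c(tnames, background$strains$name[bamp])
    copies <- c(copies, background$strains$copies[bamp])
  }
  if (cfg$depth > 0 && length(templates) == 0) {
    stop("no amplifiable strains and no background: nothing to sequence")
  }
  expected <- if (length(copies)) setNames(copies / sum(copies), tnames)
              else numeric(0)
  n <- cfg$depth
  if (n == 0) {
    return(list(batch = read_batch(character(0), character(0), character(0),
                                   index = character(0)),
                truth = data.frame(read_id = character(0),
                                   template_id = character(0),
                                   sample_id = character(0),
                                   is_chimera = logical(0)),
                expected_proportions = expected))
  }
  draw <- sample(seq_along(templates), n, replace = TRUE,
                 prob = copies / sum(copies))
  is_chim <- runif(n) < cfg$chimera_rate & length(templates) >= 2
  r1 <- character(n); r2 <- character(n)
  q1 <- character(n); q2 <- character(n)
  tid <- character(n)
  rl <- cfg$read_length
  qhi <- "G"; qlo <- "5"   # Phred+33 for Q38 / Q20
  for (i in seq_len(n)) {
    if (is_chim[i]) {
      pair <- sample(seq_along(templates), 2, prob = copies / sum(copies))
      while (pair[1] == pair[2] && length(templates) > 1) {
        pair <- sample(seq_along(templates), 2, prob = copies / sum(copies))
      }
      a <- templates[pair[1]]; b <- templates[pair[2]]
      cx <- sample(seq_len(min(nchar(a), nchar(b)) - 1L), 1)
      tmpl <- paste0(substr(a, 1, cx), substr(b, cx + 1L, nchar(b)))
      tid[i] <- paste0("chimera:", tnames[pair[1]], "+", tnames[pair[2]])
    } else {
      tmpl <- templates[draw[i]]
      tid[i] <- tnames[draw[i]]
    }
    er <- apply_errors(tmpl, cfg$substitution_rate, cfg$indel_rate)
    sq <- er$seq
    len <- nchar(sq)
    l1 <- min(rl, len); l2 <- min(rl, len)
    r1[i] <- substr(sq, 1, l1)
    e1 <- er$errored[seq_len(l1)]
    q1[i] <- paste(ifelse(e1, qlo, qhi), collapse = "")
    r2[i] <- substr(sq, len - l2 + 1L, len)   # reverse-complemented below
    e2 <- rev(er$errored[(len - l2 + 1L):len])
    q2[i] <- paste(ifelse(e2, qlo, qhi), collapse = "")
  }
  r2 <- dna_revcomp_many(r2)
  ids <- sprintf("sim:%s:%06d:%s", cfg$sample_id, seq_len(n), cfg$index)
  batch <- read_batch(ids, r1, r2, q1, q2,
                      index = rep(cfg$index, n))
  truth <- data.frame(read_id = ids, template_id = tid,
                      sample_id = cfg$sample_id, is_chimera = is_chim)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_fastq(batch, file.path(dir, "r1.fastq.gz"),
                file.path(dir, "r2.fastq.gz"))
  }
  list(batch = batch, truth = truth, expected_proportions = expected)
}

#' Write a read batch as paired FASTQ files
#'
#' @param batch a `read_batch`.
#' @param r1_path,r2_path output paths (gzipped when ending in `.gz`).
#' @export
write_fastq <- function(batch, r1_path, r2_path) {
  wr <- function(path, seqs, quals, ids) {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
    on.exit(close(con))
    if (length(seqs)) {
      writeLines(paste0("@", ids, "\n", seqs, "\n+\n", quals), con)
    }
  }
  wr(r1_path, batch$r1, batch$q1, paste0(batch$id, "/1"))
  wr(r2_path, batch$r2, batch$q2, paste0(batch$id, "/2"))
  invisible(batch)
}

#' Simulate a dilution series with constant background
#'
#' One run per grid point with the mock strain copies set to the grid value
#' and the contaminant background held constant, plus a negative (water)
#' control with zero strain copies — the simulated analog of sequencing a
#' serial dilution from 10 to 10^7 copies per strain.
#'
#' @param spec a `mock_spec`.
#' @param copies_grid per-strain copy numbers (default `10^(1:7)`).
#' @param background a `mock_spec` of contaminants ([synth_background()]).
#' @param cfg base [seq_run_config()]; per-run seeds are derived from
#'   `cfg$seed`.
#' @return Named list of [simulate_run()] results (`copies_<n>` plus
#'   `negative_control`).
#' @export
dilution_series <- function(spec, copies_grid = 10^(1:7), background,
                            cfg = seq_run_config()) {
  runs <- list()
  for (k in seq_along(copies_grid)) {
    sp <- spec
    sp$strains$copies <- rep(copies_grid[k], nrow(sp$strains))
    rc <- cfg
    rc$seed <- cfg$seed + k
    rc$sample_id <- sprintf("copies_%g", copies_grid[k])
    runs[[rc$sample_id]] <- simulate_run(sp, rc, background = background)
  }
  sp <- spec
  sp$strains$copies <- rep(0, nrow(sp$strains))
  rc <- cfg
  rc$seed <- cfg$seed + length(copies_grid) + 1L
  rc$sample_id <- "negative_control"
  runs$negative_control <- simulate_run(sp, rc, background = background)
  runs
}
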