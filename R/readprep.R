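# FASTQ ingestion, zero-mismatch demultiplexing, and overlap-based read-pair
# joining. Joining is the pipeline's only sequence-quality filter: no a priori
# trimming on Illumina quality scores is ever applied; poor pairs are removed
# because their overlap exceeds the mismatch-density ceiling.

# Printed primer/adapter segments of the two-step library design. The first
# PCR targets the V3-V4 region with short fusion primers; the second PCR adds
# the flow-cell adapters and the 6-base sample index.
PRIMER_FWD <- "TCCTACGGGAGGCAGCAGT"
PRIMER_REV <- "GGACTACCAGGGTATCTAATCCTGTT"
PCR2_P5_TAIL <- "AATGATACGGCGACCACCGAGATCTACACT"   # added 5' of the P5 side
PCR2_P7_TAIL <- "CAAGCAGAAGACGGCATACGAGAT"         # added 5' of the P7 side
PCR2_INDEX_LEN <- 6L
PCR2_SPACER <- "GTGACT"                            # between index and primer

#' Sequenced-region and library-length arithmetic
#'
#' The sequenced 16S region is 467 bp; the first PCR yields a 522 bp product
#' (region plus primer tails) and the second PCR adds the P5/P7 adapter
#' segments, the 6-base index and its spacer.
#'
#' @param pcr1_length length of the first-round PCR product in bp
#'   (default 522).
#' @return Length in bp of the second-round (final library) product.
#' @export
#' @examples
#' pcr2_product_length()  # 588
pcr2_product_length <- function(pcr1_length = 522L) {
  pcr1_length + nchar(PCR2_P5_TAIL) + nchar(PCR2_P7_TAIL) +
    PCR2_INDEX_LEN + nchar(PCR2_SPACER)
}

#' Expected read-pair overlap for a sequenced region
#'
#' For paired reads of `read_length` covering a region of `region_length`,
#' the overlap of the two mates is `2 * read_length - region_length`
#' (33 bp for 2x250 reads over 467 bp; 133 bp for 2x300 reads).
#'
#' @param read_length length of each mate in bp.
#' @param region_length length of the sequenced region in bp.
#' @return Integer overlap length in bp.
#' @export
expected_overlap <- function(read_length, region_length) {
  ov <- 2L * as.integer(read_length) - as.integer(region_length)
  if (ov <= 0) {
    stop("reads of ", read_length, " bp cannot overlap over a ",
         region_length, " bp region")
  }
  ov
}

#' Pair-joining configuration
#'
#' Presets follow the MiSeq kit in use: v2 (2x250) joins overlaps of 10-70 bp,
#' v3 (2x300) 110-170 bp; both reject pairs whose best overlap has a mismatch
#' density above 0.1.
#'
#' @param kit `"v2"`, `"v3"`, or `NULL` to give explicit bounds.
#' @param min_overlap,max_overlap overlap scan bounds in bp.
#' @param max_mismatch_density maximum fraction of mismatching positions in
#'   the accepted overlap.
#' @return A `join_config` list.
#' @export
join_config <- function(kit = NULL, min_overlap = NULL, max_overlap = NULL,
                        max_mismatch_density = 0.1) {
  if (!is.null(kit)) {
    kit <- match.arg(kit, c("v2", "v3"))
    preset <- switch(kit, v2 = c(10L, 70L), v3 = c(110L, 170L))
    min_overlap <- min_overlap %||% preset[1]
    max_overlap <- max_overlap %||% preset[2]
  }
  if (is.null(min_overlap) || is.null(max_overlap)) {
    stop("give a kit preset or explicit overlap bounds")
  }
  if (min_overlap <= 0 || min_overlap > max_overlap) {
    stop("require 0 < min_overlap <= max_overlap")
  }
  if (max_mismatch_density < 0 || max_mismatch_density > 1) {
    stop("max_mismatch_density must lie in [0, 1]")
  }
  structure(list(min_overlap = as.integer(min_overlap),
                 max_overlap = as.integer(max_overlap),
                 max_mismatch_density = max_mismatch_density),
            class = "join_config")
}

#' Read a batch of paired FASTQ files
#'
#' @param r1_path,r2_path FASTQ (optionally gzipped) paths for the two mates.
#' @param index_path optional third FASTQ carrying the index read; when
#'   absent, the index is taken from the last `:`-separated field of the read
#'   header.
#' @return A `read_batch`: list with `id`, `r1`, `r2` (character), `q1`, `q2`
#'   (list of integer Phred vectors is avoided: character Phred+33 strings),
#'   and `index`.
#' @export
read_fastq_pairs <- function(r1_path, r2_path, index_path = NULL) {
  rd <- function(p) {
    x <- Biostrings::readDNAStringSet(p, format = "fastq", with.qualities = TRUE)
    list(id = names(x),
         seq = unname(as.character(x)),
         qual = unname(as.character(S4Vectors::mcols(x)$qualities)))
  }
  a <- rd(r1_path); b <- rd(r2_path)
  if (length(a$seq) != length(b$seq)) stop("mate files differ in read count")
  ids <- sub("/[12]$", "", sub(" .*", "", a$id))
  idx <- if (!is.null(index_path)) {
    toupper(rd(index_path)$seq)
  } else {
    # header dialect: last ':'-separated field of the read id
    vapply(strsplit(ids, ":", fixed = TRUE),
           function(f) toupper(f[length(f)]), character(1))
  }
  structure(list(id = ids, r1 = a$seq, r2 = b$seq,
                 q1 = a$qual, q2 = b$qual, index = idx),
            class = "read_batch")
}

#' @export
print.read_batch <- function(x, ...) {
  cat("read_batch:", length(x$r1), "read pairs\n")
  invisible(x)
}

read_batch <- function(id, r1, r2, q1 = NULL, q2 = NULL, index = NULL) {
  q1 <- q1 %||% vapply(nchar(r1), function(n) strrep("G", n), character(1))
  q2 <- q2 %||% vapply(nchar(r2), function(n) strrep("G", n), character(1))
  structure(list(id = id, r1 = r1, r2 = r2, q1 = q1, q2 = q2,
                 index = index %||% rep(NA_character_, length(r1))),
            class = "read_batch")
}

subset_batch <- function(batch, i) {
  structure(lapply(unclass(batch), `[`, i), class = "read_batch")
}

#' Demultiplex read pairs by exact index match
#'
#' A pair is assigned to a sample only when its index sequence matches one of
#' the panel's indexes exactly (case-insensitive); no mismatches are tolerated,
#' so reads with sequencing errors in the index (including any N) fall into
#' the unassigned pool.
#'
#' @param batch a `read_batch`.
#' @param panel_map named character vector: names are 6-mer index sequences,
#'   values are sample ids.
#' @return List with `samples` (named list of `read_batch` per sample),
#'   `unassigned` (a `read_batch`), and `counts` (data.frame).
#' @export
demultiplex <- function(batch, panel_map) {
  keys <- toupper(names(panel_map))
  for (k in keys) validate_index(k)
  if (anyDuplicated(keys)) stop("duplicate index sequences in panel map")
  if (anyDuplicated(unname(panel_map))) {
    stop("two indexes map to the same sample id")
  }
  idx <- toupper(batch$index)
  sample_of <- setNames(unname(panel_map), keys)[idx]
  assigned <- !is.na(sample_of)
  samples <- lapply(setNames(nm = unname(panel_map)), function(s) {
    subset_batch(batch, which(assigned & sample_of == s))
  })
  counts <- data.frame(
    sample_id = c(unname(panel_map), "unassigned"),
    reads = c(vapply(samples, function(b) length(b$r1), integer(1)),
              sum(!assigned)))
  list(samples = samples,
       unassigned = subset_batch(batch, which(!assigned)),
       counts = counts)
}

# Vectorized joining core: for every candidate overlap L, mismatches between
# the tail of r1 and the head of revcomp(r2). Equal-length mates per call.
join_batch_core <- function(r1, rc2, q1, rq2, cfg) {
  n <- length(r1)
  len1 <- nchar(r1[1]); len2 <- nchar(rc2[1])
  m1 <- seq_int_matrix(r1); m2 <- seq_int_matrix(rc2)
  lo <- cfg$min_overlap; hi <- min(cfg$max_overlap, len1, len2)
  if (hi < lo) {
    return(list(ok = rep(FALSE, n), reason = rep("no-overlap", n)))
  }
  cand <- lo:hi
  mism <- matrix(NA_real_, n, length(cand))
  for (j in seq_along(cand)) {
    L <- cand[j]
    a <- m1[, (len1 - L + 1L):len1, drop = FALSE]
    b <- m2[, 1:L, drop = FALSE]
    # N (code 5) counts as a mismatch against anything, including N
    diff <- a != b | a == 5L | b == 5L
    mism[, j] <- rowSums(diff)
  }
  dens <- sweep(mism, 2, cand, "/")
  # minimal density; ties -> longer overlap
  pick <- apply(dens, 1, function(d) {
    j <- which(d <= min(d) + 1e-12)
    j[length(j)]
  })
  best_L <- cand[pick]
  best_mm <- mism[cbind(seq_len(n), pick)]
  best_dens <- dens[cbind(seq_len(n), pick)]
  ok <- best_dens <= cfg$max_mismatch_density + 1e-12
  list(ok = ok, reason = ifelse(ok, NA_character_, "density-exceeded"),
       overlap = best_L, mismatches = as.integer(best_mm),
       m1 = m1, m2 = m2, q1 = q1, rq2 = rq2)
}

merge_one <- function(v1, v2, qv1, qv2, L) {
  len1 <- length(v1)
  ov1 <- (len1 - L + 1L):len1
  ov2 <- 1:L
  cons <- v1[ov1]
  mm <- which(v1[ov1] != v2[ov2] | v1[ov1] == 5L | v2[ov2] == 5L)
  for (p in mm) {
    a <- v1[ov1[p]]; b <- v2[ov2[p]]
    if (a == 5L && b != 5L) { cons[p] <- b; next }   # take the non-N base
    if (b == 5L) next                                # keep r1's base
    # higher quality wins; tie -> r1's base
    cons[p] <- if (qv2[ov2[p]] > qv1[ov1[p]]) b else a
  }
  int_to_seq(c(v1[seq_len(len1 - L)], cons, v2[(L + 1L):length(v2)]))
}

#' Join read pairs by their overlap
#'
#' Reverse-complements mate 2, scans all overlap lengths within the
#' configuration bounds, and keeps the overlap with minimal mismatch density
#' (ties go to the longer overlap). The pair is accepted only when that
#' density does not exceed `max_mismatch_density`; within the overlap,
#' mismatching positions take the base with the higher quality score
#' (tie: mate 1's base).
#'
#' @param batch a `read_batch` (all mates of equal length per mate).
#' @param cfg a [join_config()].
#' @param sample_id sample label stored on the joined sequences.
#' @return List with `joined` (data.frame: `seq_id`, `sequence`, `sample_id`,
#'   `overlap_length`, `overlap_mismatches`) and `rejects` (data.frame:
#'   `seq_id`, `reason`).
#' @export
join_pairs <- function(batch, cfg, sample_id = NA_character_) {
  n <- length(batch$r1)
  if (n == 0) {
    return(list(joined = data.frame(seq_id = character(0),
                                    sequence = character(0),
                                    sample_id = character(0),
                                    overlap_length = integer(0),
                                    overlap_mismatches = integer(0)),
                rejects = data.frame(seq_id = character(0),
                                     reason = character(0))))
  }
  if (length(unique(nchar(batch$r1))) > 1 ||
      length(unique(nchar(batch$r2))) > 1) {
    # mixed lengths: process per length class
    key <- paste(nchar(batch$r1), nchar(batch$r2))
    parts <- lapply(split(seq_len(n), key), function(i) {
      join_pairs(subset_batch(batch, i), cfg, sample_id)
    })
    return(list(joined = do.call(rbind, lapply(parts, `[[`, "joined")),
                rejects = do.call(rbind, lapply(parts, `[[`, "rejects"))))
  }
  rc2 <- dna_revcomp_many(batch$r2)
  rq2 <- vapply(batch$q2, function(q) intToUtf8(rev(utf8ToInt(q))),
                character(1), USE.NAMES = FALSE)
  core <- join_batch_core(batch$r1, rc2, batch$q1, rq2, cfg)
  ok <- which(core$ok)
  seqs <- character(length(ok))
  for (t in seq_along(ok)) {
    i <- ok[t]
    seqs[t] <- merge_one(core$m1[i, ], core$m2[i, ],
                         utf8ToInt(batch$q1[i]) - 33L,
                         utf8ToInt(rq2[i]) - 33L,
                         core$overlap[i])
  }
  list(joined = data.frame(seq_id = batch$id[ok],
                           sequence = seqs,
                           sample_id = rep(sample_id, length(ok)),
                           overlap_length = core$overlap[ok],
                           overlap_mismatches = core$mismatches[ok]),
       rejects = data.frame(seq_id = batch$id[!core$ok],
                            reason = core$reason[!core$ok]))
}

#' Join a single read pair
#'
#' Scalar convenience wrapper around [join_pairs()].
#'
#' @param r1,r2 mate sequences (r2 in sequencing orientation).
#' @param q1,q2 optional Phred+33 quality strings; constant high quality when
#'   omitted.
#' @param cfg a [join_config()].
#' @return One-row data.frame as in [join_pairs()], or `NULL` when the pair
#'   is rejected; the rejection's reason code is available from
#'   [join_pairs()]'s `rejects` table.
#' @export
join_pair <- function(r1, r2, cfg, q1 = NULL, q2 = NULL) {
  b <- read_batch("pair1", r1, r2, q1, q2)
  res <- join_pairs(b, cfg)
  if (nrow(res$joined) == 1) res$joined else NULL
}

#' Write joined sequences as FASTA
#'
#' @param joined data.frame from [join_pairs()].
#' @param file output path.
#' @export
write_joined_fasta <- function(joined, file) {
  x <- Biostrings::DNAStringSet(joined$sequence)
  names(x) <- joined$seq_id
  Biostrings::writeXStringSet(x, file)
  invisible(file)
}
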