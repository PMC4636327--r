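# End-to-end orchestration: demultiplex -> join -> dereplicate -> align and
# cull -> blunt trim -> precluster (+ singleton removal) -> chimera screen ->
# classify (+ non-Bacteria filter) -> distance + average-neighbor OTU
# clustering -> consensus taxonomy -> OTU table, with a per-stage read
# attrition ledger.

#' Pipeline run configuration
#'
#' Collects every stage parameter with its conventional default: 2x250 kit
#' preset joining (mismatch density 0.1), precluster at 3 differences,
#' chimera score threshold 0.28 with abundance skew 2, classifier bootstrap
#' cutoff 80%, OTU distance cutoff 0.03, consensus cutoff 51%.
#'
#' @param kit MiSeq kit preset, `"v2"` or `"v3"`.
#' @param max_mismatch_density pair-joining density ceiling.
#' @param precluster_diffs merge radius of the pre-clustering step.
#' @param chimera_chunks,chimera_skew,chimera_threshold chimera-screen knobs.
#' @param classifier_cutoff bootstrap confidence cutoff (percent).
#' @param classifier_bootstraps bootstrap rounds.
#' @param otu_cutoff average-neighbor distance cutoff.
#' @param consensus_cutoff OTU consensus agreement (percent).
#' @param min_identity,min_coverage alignment cull thresholds.
#' @param seed integer seed for the classifier bootstraps.
#' @return A `run_config` list.
#' @export
run_config <- function(kit = "v2", max_mismatch_density = 0.1,
                       precluster_diffs = 3L, chimera_chunks = 4L,
                       chimera_skew = 2.0, chimera_threshold = 0.28,
                       classifier_cutoff = 80, classifier_bootstraps = 100L,
                       otu_cutoff = 0.03, consensus_cutoff = 51,
                       min_identity = 0.5, min_coverage = 0.5, seed = 1L) {
  structure(list(kit = kit, max_mismatch_density = max_mismatch_density,
                 precluster_diffs = precluster_diffs,
                 chimera_chunks = chimera_chunks,
                 chimera_skew = chimera_skew,
                 chimera_threshold = chimera_threshold,
                 classifier_cutoff = classifier_cutoff,
                 classifier_bootstraps = classifier_bootstraps,
                 otu_cutoff = otu_cutoff,
                 consensus_cutoff = consensus_cutoff,
                 min_identity = min_identity, min_coverage = min_coverage,
                 seed = as.integer(seed)),
            class = "run_config")
}

empty_pipeline_result <- function(ledger) {
  list(otu_table = list(counts = matrix(0L, 0, 0), lineage = NULL,
                        otus = list(), empty = TRUE),
       assignments = NULL, uniques = NULL, verdicts = NULL,
       ledger = ledger)
}

#' Run the full analysis pipeline
#'
#' @param batches either a single `read_batch` (already per-sample) or a
#'   named list of `read_batch` per sample; use [demultiplex()] upstream for
#'   multiplexed input.
#' @param ref a `reference_alignment` for the screening step.
#' @param model a trained `word_model` for classification.
#' @param cfg a [run_config()].
#' @param panel_map optional named index -> sample map; when given together
#'   with a single multiplexed `read_batch`, demultiplexing runs first and
#'   the assigned count is recorded in the ledger.
#' @return List with `otu_table`, `assignments`, `uniques` (the clean
#'   working set), `verdicts` (chimera report), and `ledger` (data.frame of
#'   per-stage read counts).
#' @export
run_pipeline <- function(batches, ref, model, cfg = run_config(),
                         panel_map = NULL) {
  ledger <- data.frame(stage = character(0), reads = numeric(0))
  note <- function(stage, reads) {
    ledger <<- rbind(ledger, data.frame(stage = stage, reads = reads))
  }
  if (inherits(batches, "read_batch")) {
    if (!is.null(panel_map)) {
      note("raw_pairs", length(batches$r1))
      dmx <- demultiplex(batches, panel_map)
      batches <- dmx$samples
      note("assigned",
           sum(vapply(batches, function(b) length(b$r1), integer(1))))
    } else {
      batches <- list(sample1 = batches)
    }
  }
  jcfg <- join_config(kit = cfg$kit,
                      max_mismatch_density = cfg$max_mismatch_density)
  if (!any(ledger$stage == "raw_pairs")) {
    raw <- sum(vapply(batches, function(b) length(b$r1), integer(1)))
    note("raw_pairs", raw)
  }
  joined <- do.call(rbind, lapply(names(batches), function(s) {
    join_pairs(batches[[s]], jcfg, sample_id = s)$joined
  }))
  if (is.null(joined)) joined <- data.frame(sequence = character(0),
                                            sample_id = character(0))
  note("joined", nrow(joined))
  uniques <- dereplicate(joined)
  if (nrow(uniques) == 0) {
    note("aligned", 0); note("post_precluster", 0); note("post_singleton", 0)
    note("post_chimera", 0); note("bacterial", 0); note("clustered", 0)
    return(empty_pipeline_result(ledger))
  }
  scr <- cull_nonspecific(uniques, ref, min_identity = cfg$min_identity,
                          min_coverage = cfg$min_coverage)
  note("aligned", sum(scr$kept$total_count))
  if (nrow(scr$kept) == 0) {
    note("post_precluster", 0); note("post_singleton", 0)
    note("post_chimera", 0); note("bacterial", 0); note("clustered", 0)
    return(empty_pipeline_result(ledger))
  }
  tb <- trim_blunt(scr$kept)
  blunt <- merge_trimmed_duplicates(tb$trimmed)
  pc <- precluster(blunt, max_diffs = cfg$precluster_diffs,
                   remove_singletons = FALSE)
  note("post_precluster", pc$reads_out)
  merged <- pc$merged
  singles <- merged$total_count == 1L
  work <- merged[!singles, , drop = FALSE]
  note("post_singleton", sum(work$total_count))
  if (nrow(work) == 0) {
    note("post_chimera", 0); note("bacterial", 0); note("clustered", 0)
    return(empty_pipeline_result(ledger))
  }
  verdicts <- screen_chimeras(work, chunks = cfg$chimera_chunks,
                              skew = cfg$chimera_skew,
                              score_threshold = cfg$chimera_threshold)
  chi <- apply_chimera_verdicts(work, verdicts)
  note("post_chimera", chi$reads_out)
  work <- chi$kept
  assignments <- classify_uniques(work, model,
                                  bootstraps = cfg$classifier_bootstraps,
                                  cutoff = cfg$classifier_cutoff,
                                  seed = cfg$seed)
  bac <- filter_non_bacteria(work, assignments)
  note("bacterial", bac$reads_out)
  work <- bac$kept
  if (nrow(work) == 0) {
    note("clustered", 0)
    return(empty_pipeline_result(ledger))
  }
  dm <- distance_matrix(work)
  otus <- cluster_average_neighbor(dm, cutoff = cfg$otu_cutoff,
                                   counts = setNames(work$total_count,
                                                     work$seq_id))
  table <- build_otu_table(otus, work, assignments,
                           consensus_cutoff = cfg$consensus_cutoff)
  note("clustered", sum(table$counts))
  list(otu_table = table, assignments = assignments, uniques = work,
       verdicts = verdicts, ledger = ledger)
}

#' Render the attrition ledger as a percentage report
#'
#' Percentages are given relative to the raw pair count, in the style of
#' per-stage sequencing yield reports.
#'
#' @param ledger data.frame from [run_pipeline()].
#' @param file optional TSV output path.
#' @return data.frame with `stage`, `reads`, `pct_of_raw`.
#' @export
attrition_report <- function(ledger, file = NULL) {
  raw <- ledger$reads[ledger$stage == "raw_pairs"]
  out <- data.frame(stage = ledger$stage, reads = ledger$reads,
                    pct_of_raw = if (length(raw) && raw > 0) {
                      round(100 * ledger$reads / raw, 2)
                    } else 0)
  if (!is.null(file)) {
    write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
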