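#!/usr/bin/env Rscript
# Regenerates the bundled miniature synthetic reference files under
# inst/extdata/: a gapped 16S-like reference alignment and the matching
# six-rank taxonomy. Deterministic (seed 1 mock strains + seed 99
# contaminants); three strains carry a 3-base deletion so the alignment has
# real gap columns.

suppressPackageStartupMessages(library(tissamp16s))

spec <- synth_reference_set(14, seed = 1)
bg <- synth_background(seed = 99)
pcr <- in_silico_pcr(spec)
bpcr <- in_silico_pcr(bg)
seqs <- c(substr(spec$strains$sequence, pcr$start, pcr$end),
          substr(bg$strains$sequence, bpcr$start, bpcr$end))
ids <- c(spec$strains$name, bg$strains$name)

# introduce a shared 3-column gap region: strains 5-7 lose 3 bases at
# position 200 of the amplicon; all other rows keep their bases there
gapped <- vapply(seq_along(seqs), function(i) {
  if (i %in% 5:7) {
    paste0(substr(seqs[i], 1, 199), "---", substr(seqs[i], 203, nchar(seqs[i])))
  } else seqs[i]
}, character(1))

dir.create("inst/extdata", showWarnings = FALSE, recursive = TRUE)
fa <- file("inst/extdata/synthetic_reference_alignment.fasta", "w")
for (i in seq_along(gapped)) {
  writeLines(c(paste0(">", ids[i]), gapped[i]), fa)
}
close(fa)

tax <- rbind(
  data.frame(seq_id = spec$taxonomy$seq_id,
             lineage = paste0(apply(spec$taxonomy[, c("domain", "phylum",
                                                      "class", "order",
                                                      "family", "genus")],
                                    1, paste, collapse = ";"), ";")),
  data.frame(seq_id = bg$taxonomy$seq_id,
             lineage = paste0(apply(bg$taxonomy[, c("domain", "phylum",
                                                    "class", "order",
                                                    "family", "genus")],
                                    1, paste, collapse = ";"), ";")))
write.table(tax, "inst/extdata/synthetic_taxonomy.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE, col.names = FALSE)

seqtab <- rbind(
  data.frame(seq_id = spec$taxonomy$seq_id, sequence = spec$taxonomy$sequence),
  data.frame(seq_id = bg$taxonomy$seq_id, sequence = bg$taxonomy$sequence))
fa2 <- file("inst/extdata/synthetic_taxonomy_sequences.fasta", "w")
for (i in seq_len(nrow(seqtab))) {
  writeLines(c(paste0(">", seqtab$seq_id[i]), seqtab$sequence[i]), fa2)
}
close(fa2)
cat("wrote inst/extdata files\n")
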