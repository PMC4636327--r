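---
title: "Methods: the tissamp16s pipeline, its parameters, and its validation harness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the tissamp16s pipeline, its parameters, and its validation harness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tissamp16s)
```

# Scope and model

`tissamp16s` profiles bacterial communities from paired-end MiSeq reads of a
467 bp 16S rDNA region (V3–V4). It is built for low-biomass tissue samples,
where three assumptions drive the design:

* the dominant nuisance signals are non-specific amplification of host DNA
  and bacterial DNA contaminating PCR reagents, not low base quality;
* MiSeq errors are almost exclusively substitutions (~0.1% per base;
  indels < 0.001%), random in position, so at adequate depth erroneous
  reads sit within a few differences of an abundant true sequence;
* quantitative claims must be validated against communities of known
  composition, because every processing step can distort abundances.

Consequently the pipeline never filters on Illumina quality scores (their
error probabilities are unreliable for low-quality calls, and trimming can
destroy the overlap); quality control happens through pair-joining
consistency, reference-alignment screening, abundance-ranked denoising and
chimera removal.

# Stage parameters

| Stage | Parameter | Default | Rationale |
|---|---|---|---|
| join | min/max overlap (v2) | 10 / 70 bp | 2×250 reads over 467 bp overlap by 33 bp |
| join | min/max overlap (v3) | 110 / 170 bp | 2×300 reads overlap by 133 bp |
| join | max mismatch density | 0.1 | fraction of mismatching overlap positions |
| screen | cull thresholds | identity ≥ 0.5, coverage ≥ 0.5 | identity = matches / global-alignment length; random DNA scores ≈ 0.47 under the +1/−1, gap −2/−1 scoring, genuine 16S far above |
| precluster | merge radius | 3 differences | expected errors per 467 bp read at 0.1% ≈ 0.47; reads with ≥ 4 errors are rare and fall to singleton removal |
| chimera | score threshold | 0.28 | `Y/(Y + 8N + 0.5)` vote score of the two-parent model |
| chimera | abundance skew | 2 | parents must be ≥ 2× the query's abundance |
| classify | word size / bootstraps | 8 / 100 | distinct-word presence, `⌊W/8⌋` words per bootstrap |
| classify | confidence cutoff | 80% | per rank; sub-cutoff ranks become "unclassified" |
| cluster | distance cutoff | 0.03 | average-neighbor OTUs at 97% identity |
| consensus | agreement cutoff | 51% | abundance-weighted per-rank vote |
| diversity | rarefaction | step 100, 1000 resamples | empirical mean richness per depth |
| diversity | UniFrac alpha | 0.6 preset (0.2 for tissue ordinations) | weight of abundant lineages |
| profile | pooling threshold | 0.5% mean proportion | "other (<0.5%)" display category |

All are exposed through `run_config()` or the individual stage functions.

# Numerical and algorithmic choices

**Pair joining.** Mate 2 is reverse-complemented; every overlap length
within the kit bounds is scored; minimal mismatch density wins, ties go to
the longer overlap (more evidence at equal density). At overlap mismatches
the base with the higher quality score is kept (tie: mate 1); N counts as a
mismatch and loses to any called base. Rejections carry reason codes
(`no-overlap`, `density-exceeded`).

**Alignment screening.** The template is chosen by shared distinct 8-mer
count (tie: lexicographically smallest template id); the query is globally
aligned to the ungapped template (match +1, mismatch −1, gap open −2,
extend −1, via Biostrings) and projected into the template's alignment
columns, NAST-style: bases inserted relative to the template are dropped
and counted, deletions appear as `-`. This puts every sequence into one
column space, which pre-clustering and distance calculation require. A
query whose length equals the template's skips dynamic programming and is
compared position-wise — with substitution-dominated MiSeq chemistry this
covers ~99.5% of reads. Identity is matches over alignment length; the 0.5
identity/coverage culls are this package's operationalization of "does not
align" and are configurable.

**Blunt trimming.** The common span is `[max(start columns), min(end
columns)]`; with it, all retained sequences cover identical columns.
Trimming can merge previously distinct sequences, so the pipeline
re-dereplicates afterwards.

**Difference counting conventions.** Pre-clustering counts every gap column
aligned to a base as one difference (per-column rule). OTU distances
instead run-compress: a contiguous gap run counts once (one indel event),
and the compared length counts that run as one position, with shared-gap
columns skipped. The two stages deliberately use different conventions —
pre-clustering absorbs point errors, distances estimate evolutionary
divergence — mirroring the two defaults of the environments these steps
descend from.

**Chimera screen.** Queries are processed in increasing abundance;
candidate parents are unflagged sequences with ≥ `skew` times the query's
abundance. Three guards qualify a candidate model beyond the vote score:

* *parent identity floor* (default 0.8): parents must be within 20% column
  divergence of the query. A chimera's parents are, by construction,
  near-copies of the query over their segments; without the floor two
  mutually unrelated abundant sequences (e.g. reagent contaminants vs mock
  strains) can "explain" a divergent query better than any single parent.
* *minimum improvement* (`min_div` = 0.008 of columns, ≈ 4 columns at
  467): a one-column improvement arises by chance whenever a private
  substitution near a terminus coincides with a third sequence's base.
* *model identity cap* (`max_model_mismatch_frac` = 0.01): the two-parent
  model must reconstruct the query up to sequencing-error scale. This is
  the counterpart of requiring high query–model identity: a "model" that
  still leaves dozens of columns unexplained is a coincidental improvement
  between unrelated sequences, not chimeric structure.

The crossover search itself is exhaustive over all column boundaries. The
chunked best-parents-per-block shortlist — the cited heuristic for large
databases — only activates above 64 candidate parents; below that the full
parent set is searched, since block-level shortlists can miss the minor
parent of a near-terminal crossover. Flagged queries are removed and never
serve as parents.

**Classifier.** Priors `(n_w + 0.5)/(N + 1)` and genus conditionals
`(m_w + prior)/(M + 1)` over distinct 8-mers of the given strand (the
screening stage orients reads). Scores are sums of log conditionals;
argmax ties break to the lexicographically smallest genus name. Bootstrap
confidence resamples `⌊W/8⌋` of the `W` distinct words with replacement,
100 times, with a per-sequence seed derived from the run seed, so results
are bit-reproducible. The 80% cutoff applies at every rank, and a failed
rank silences all deeper ranks (hierarchical consistency).

**Average-neighbor clustering.** Agglomerative with the exact average
criterion (cluster sizes weight the linkage update, so inter-cluster
distance is always the mean over all cross pairs). Ties break on the
lexicographically smallest sorted pair of cluster labels (a cluster's label
is its smallest member id), making the partition bit-stable. Note the 97%
identity convention: a cutoff passed as 0.0003 (a literal "0.03% identity"
reading) triggers a warning, since the universal convention is distance
0.03. The partition at a smaller cutoff is always a refinement of the
partition at a larger one (property-tested).

**Diversity.** The OTU tree for generalized UniFrac is neighbor joining on
the representatives' run-compressed distances, midpoint-rooted, negative NJ
branches clamped to 0 — the tree construction is this package's choice
(the formula needs *a* tree; none is canonical for OTU representatives),
and UniFrac values depend on it, so analyses should use this tree
consistently rather than comparing numbers across tools. PCoA uses Gower
double-centering, symmetric eigendecomposition, coordinates scaled by
√(positive eigenvalues); negative eigenvalues are reported and their axes
dropped; per-axis sign is fixed by making the largest-magnitude loading
positive. Rarefaction draws one random permutation per resample and reads
richness at every depth from the first-occurrence positions, which is
equivalent to independent subsampling without replacement at each depth and
makes 1000 resamples affordable at any depth. The heatmap-style export uses
`log10(p + ε)`, ε one tenth of the smallest nonzero proportion.

**Degenerate inputs.** Empty read sets flow through the whole pipeline and
produce an empty OTU table plus a complete zero ledger. A panel of fewer
than ~8 indexes cannot meet the composition bands, so tiny panels must be
requested with `check_balance = FALSE`. Trimming with no common column span
and classifying sequences shorter than the word size raise errors.

# Index design

Candidate generation scans all 4⁶ = 4096 hexamers in lexicographic order,
accepting each one compatible with everything accepted before it (Hamming
distance ≥ 2, not the complement, not the reverse complement). The scan
order is fixed for determinism; other orders produce different (equally
valid) pools, so the candidate count (832 under this order) is a property
of the order, not a universal constant. Selection minimizes
`Σ_pos |f_{A∪C} − 0.5| + Σ_pos Σ_base (f_base − 0.25)²`
by greedy construction plus best-improving swap refinement with
lexicographic tie-breaks; the A/C-vs-T/G channel term reflects the two
excitation LEDs the MiSeq camera calibrates on, the base-fraction term the
"close to 25% per position" goal. The ±0.15 band on the channel fraction
and the objective itself are this package's operationalization of
"equivalent proportions"; both are configurable.

# The simulator and what passing tests mean

`synth_reference_set()` builds clade-structured 16S-like templates: a
random 422 nt core flanked by the real primer-binding sites (total 467 nt),
family ancestors at 17 fixed substitutions from a shared root and strains
at 10 from their ancestor, giving ~4% within-family and ~11% cross-family
strain divergence — inside the typical genus/family bands and safely apart
from the 3% OTU radius. Substitution counts are fixed (positions random) so
divergences cannot drift outside the bands by sampling luck. Primer dropout
plants 3 substitutions in the forward site, one beyond the in-silico PCR
tolerance of 2. Classifier training sequences are separate mutants (~1%
extra divergence), so training and test sequences are never identical.

`simulate_run()` draws reads multinomially from copy-number proportions
(mock strains plus optional background), applies substitutions (default
0.1%/base) and indels (10⁻⁵/base), cuts the mates, and emits constant
quality 38 with errored bases at 20. Constant qualities are deliberate: the
pipeline ignores quality priors, so a fitted quality model would add
nothing testable. No PCR-efficiency bias is modelled by default — the
chemistry-driven biases real mocks show (deviations of several percent)
stem from primer and polymerase effects outside this package's scope — so
recovered compositions are unbiased up to multinomial noise, and the
validation criteria (median deviation < 1 percentage point at depth 50,000;
staggered rank correlation 1.0) characterize the *pipeline's* distortion,
not the chemistry's. The reagent background defaults to five synthetic
contaminant strains from an independent root; the true contaminant load of
real reagents is unknown, so the dilution-series crossover point (where a
sample's profile collapses onto the water control) is configurable rather
than calibrated.

Study-condition defaults follow the validation designs: even mocks at 10⁷
copies per strain, 14 strains with one primer-dropout; staggered designs
spanning 10³–10⁶ copies. For the staggered acceptance experiment the
package uses 8 strains log-evenly spaced over that range: rank correlation
exactly 1.0 is only well-defined without ties in the true abundances, and
with 8 strains adjacent abundances differ by 2.7×, so rank recovery at
depth 50,000 is determined by the pipeline rather than by sampling noise.

Problem sizes in the test suite (depth 50,000 for recovery experiments,
20,000 for chimera injection, 10,000 per dilution point, 100 random
instances per oracle-equivalence check) were chosen so each experiment has
clear statistical resolution at single-CPU scale.

# Known limitations

* Alignment screening is template-projection: insertions relative to the
  chosen template are dropped (counts reported). Secondary-structure-aware
  alignment is out of scope.
* Chimera screening is de novo and single-crossover; reference-database
  screening and multi-breakpoint models are not implemented.
* Species-rank assignment is deliberately absent: short-read 16S data
  cannot support it with confidence.
* UniFrac values are tree-dependent (see above) and not numerically
  comparable with analyses built on other trees.
* The simulator does not model flow-cell optics, PhiX spike-ins, cluster
  density, or polymerase bias; its purpose is ground-truthed validation of
  the *computational* stages, not read-level realism.
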