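---
title: "Methods: droplet scRNA-seq quality control with dropkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: droplet scRNA-seq quality control with dropkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dropkit)
```

## The problem

In droplet single-cell RNA-seq (Drop-seq and its relatives), cells are
co-encapsulated with barcoded beads in a microfluidic device. Each bead
carries a 12-base cell barcode shared by all its capture oligos and a random
8-base unique molecular identifier (UMI) on each oligo, so read 1 of the
library is a 20-mer — bases 1–12 identify the putative cell, bases 13–20 the
captured molecule. Because cell loading is Poisson-limited, the overwhelming
majority of beads (over 95 % under typical dilutions) never meet a cell and
capture only ambient RNA — free-floating transcripts from damaged cells.
Three questions dominate quality control before any biology can be read off:

1. **Which barcodes are cells?** Ambient-only beads produce many barcodes
   with few reads; cell-containing beads produce few barcodes with many
   reads. Plotting the cumulative fraction of reads against barcodes ordered
   by descending read count gives a curve with a characteristic inflection —
   the *knee* — separating the two populations.
2. **How many molecules did each cell contribute?** PCR amplifies each
   captured molecule into many reads; collapsing reads to distinct UMIs per
   (barcode, gene) digitally counts molecules and yields the digital gene
   expression (DGE) matrix.
3. **Which "cells" are artifacts?** Two cells in one droplet (a *doublet*)
   merge two transcriptomes under one barcode; bare nuclei lack
   mitochondrially encoded transcripts; broken cells leak cytoplasmic mRNA
   and are dominated by mitochondrial reads.

dropkit implements these diagnostics together with a droplet-run simulator
that provides ground truth, so every stage is testable without sequencing
data.

## The simulator and what it emulates

`sim_params()` fixes the generative model; `simulate_run()` produces a
tagged-read stream, `simulate_dge()` the molecule-count matrix a perfect UMI
counter would recover from the same parameters.

Per cell-containing barcode:

* a species is drawn from the mixing proportions (two species with disjoint,
  species-prefixed gene namespaces emulate a human/mouse barnyard);
* a library size is drawn log-normal (`library_size_log_mean`,
  `library_size_log_sd`); molecules are assigned to genes multinomially from
  the species' expression profile (log-normal gene weights with sdlog
  `expression_profile_dispersion`, normalized to 1, with mitochondrial genes
  rescaled to carry exactly `mito_expression_fraction` of the mass);
* with probability `doublet_rate` a second, independently drawn cell (its
  species drawn again from the mixing proportions) shares the barcode —
  mirroring co-encapsulation;
* each molecule receives a UMI drawn uniformly over the 4^8 space, with
  collisions within a (barcode, gene) pair redrawn, and is emitted as
  `1 + Poisson(reads_per_umi_mean − 1)` duplicate reads, so every molecule
  is sequenced at least once and the read/UMI ratio converges to
  `reads_per_umi_mean`;
* ambient-only barcodes draw a few molecules from the pooled pseudobulk of
  all species (mean read yield `ambient_reads_mean`);
* finally, with probability `last_base_t_error_prob` a barcode's 12th base
  is overwritten with T. This emulates bead-synthesis errors, in which the
  final synthesis cycle reads into the oligo-dT stretch; the defect is a
  property of the bead, so all reads of an affected barcode share it, and
  any barcode collision created by the overwrite is regenerated.

Randomness is organized as one master seed from which each component
(profiles, barcodes, cell draws, ambient draws, duplication, corruption)
derives its own sub-stream, so e.g. enlarging the ambient pool does not
perturb the cell draws. Identical parameters give byte-identical output.

**Defaults.** The defaults describe a desk-scale two-species cell-line run:
100 cells against 2000 ambient barcodes (> 95 % of beads ambient-only, the
Poisson-loading regime), a median of ~8000 UMIs per cell at 3 reads per UMI
(~24,000 reads per cell, comparable to a typically sequenced cell-line
library), ~30 reads per ambient bead, 2 % of genes mitochondrial carrying
10 % of each cell's UMIs (a typical intact-cell mitochondrial load), a 5 %
doublet rate, and a 5 % T-corruption probability. The T-bias magnitude has
no published estimate — it is a free parameter chosen to be modest but
clearly visible to the diagnostic. Validation experiments in the test suite
use smaller libraries (median 300–1000 UMIs/cell, 2 reads/UMI) and 100–1000
cells so the full suite runs in well under a minute; these sizes are stated
in each test.

**What the simulator does not emulate:** sequencing errors in UMIs or read
2, realistic transcript sequences, gene–gene correlation structure,
cell-type heterogeneity within a species, ambient RNA *admixed into
cell-containing droplets*, or droplet physics beyond Poisson loading.
Passing tests therefore demonstrate algorithmic correctness under a clean
generative model, not robustness to every artifact of real libraries — in
real data the knee is blurred by ambient admixture and barcode errors, and
purity is diluted by ambient cross-species UMIs.

## Digital counting

`count_umis()` collapses tagged reads to distinct (barcode, UMI, gene)
triples by **exact string match**. Single-mismatch UMI merging, as done
inside the Drop-seq tools, is deliberately out of scope: upstream toolchains
already provide it, and exact collapse keeps the operation's specification
(set cardinality) trivially checkable against a brute-force oracle. Reads
with an `N` or a malformed barcode/UMI are dropped and tallied — low-quality
bases are diagnosed, not corrected — and reads without a gene label are
ignored for counting. The count is invariant to read order and to read
duplication by construction.

Bead-synthesis errors are likewise only *diagnosed*:
`barcode_base_composition()` reports the per-position base frequencies and
the T-excess score `freq(T, pos 12) − mean(freq(T, pos 1–11))`, whose
expectation under per-bead corruption probability *p* is `p·(1 − 1/4)`.
Correcting the affected barcodes is out of scope because the reference
correction algorithm is unspecified; the diagnostic tells you whether to
care.

## Knee detection

The inflection point of the cumulative read curve is not defined by a
formula in the field; dropkit uses a deterministic, parameter-free chord
construction: ranks are rescaled to [0, 1], the cumulative fraction is
median-smoothed (window 5 — a no-op wherever the curve is monotone, which
guards against ties and numeric noise without moving the knee), and the knee
is the rank maximizing the perpendicular distance to the chord joining the
curve's endpoints. On a step distribution this recovers the step exactly.
When the maximum distance falls below 0.05 the curve is nearly straight —
no usable cell/ambient separation — and the result is flagged `weak` rather
than silently returned. Both the window and the cutoff are exposed as
arguments. The knee is reliable when the separation ratio (median cell reads
/ median ambient reads) is large; the package's validation checks ±10 %
recovery at separation ≥ 50.

## Filtering rules and their semantics

* `filter_min_umis()` removes cells with **fewer than** `min_umis` UMIs —
  strictly: a cell at exactly the threshold is kept. The boundary matters in
  practice, so the semantics are fixed and documented rather than left to a
  comparison operator's whim. Presets by sample type are 3500 (cultured cell
  lines), 1000 (fly embryo), 300 (mouse brain), bound via `qc_profile()`.
* `filter_genes_min_count()` is the same rule on the gene margin.
* `keep_best_cells()` and `select_cells()` rank by total UMIs (or supplied
  read totals) and break ties lexicographically by barcode, making every
  selection deterministic.
* Filters are idempotent and commute, since each recomputes totals only
  along its own margin.

`cell_qc()` computes the non-mitochondrial content as
`100 × (total − mito) / total` per cell. Zero-UMI barcodes get `NA` and are
excluded from summary medians instead of erroring, because QC is routinely
run before any filtering. Candidate nuclei are flagged when the
mitochondrial percentage falls below a cutoff; "substantial mitochondrial
expression" has no canonical definition, so the default cutoff of 1 % is
deliberately conservative and is surfaced in every report. Summary medians
are computed on whatever matrix is passed in, so the user controls whether
they are pre- or post-filter; the pipeline reports them after its UMI
filter.

## The barnyard analysis

`call_species()` applies the 90 % rule: with per-species UMI counts
(u_a, u_b), purity is `max(u_a, u_b) / (u_a + u_b)`; a barcode passing the
UMI threshold is declared a singlet of the majority species when purity is
**at least** 0.90 — the boundary is inclusive, so 90 out of 100 UMIs
declares the species — and a doublet otherwise. The UMI threshold is applied
*before* classification: a barcode below it is `below_threshold`, never
`doublet`, which keeps the doublet fraction interpretable as a per-cell
rate.

Same-species doublets are invisible in a barnyard plot. Under random
pairing with mixing proportions (p, q), a fraction 2pq of doublets is
cross-species, so `summarize_barnyard()` extrapolates
`total_rate = cross_fraction / (2pq)` — at an equal mix, double the observed
fraction. This is the standard correction; its assumptions (independent
co-encapsulation, equal detectability of both species) are stated rather
than hidden. Ambient-derived cross-species UMIs are *not* subtracted before
the purity computation, so heavy ambient contamination biases the observed
doublet fraction upward; the summary records the thresholds used so this
can be judged.

## Normalization and correlation

ATPM (average transcripts per million) rescales each cell to the largest
library: counts are divided by the cell's total UMIs and multiplied by the
maximum cell total in the library. Every normalized column then sums to that
maximum; a single-cell matrix is a fixed point; zero-total cells are
excluded with a warning since their scale factor is undefined. Note that the
formula is homogeneous of degree one — multiplying all counts by a common
factor scales ATPM values by the same factor (the *relative* expression
structure is what is preserved).

Cross-sample comparisons go through `pseudobulk()` (per-gene sums across
cells — raw counts are summed first, then transformed; normalizing before
summing is intentionally not done) and `correlate_profiles()`, which subsets
both profiles to the gene intersection, applies `log2(x + 1)` (base 2 with
pseudocount 1, the field's plotting convention) and computes Pearson
correlation, reporting the intersection size alongside the coefficient. A
profile correlated with itself returns exactly 1 by identity, bypassing
floating-point round-off in the covariance. Bulk comparators are converted
with `rpkm()`, using as gene length the pre-computed mean over all isoform
lengths from the annotation table — computing that mean from a GFF is left
to upstream tooling.

## Numerical and degenerate-input choices

* UMI space is 4^8 = 65,536; collision redraw keeps molecule counts exact,
  and `simulate_dge()` may skip it because at per-gene molecule counts of a
  few dozen the collision probability is negligible and the read-level path
  redraws anyway.
* `find_knee()` requires ≥ 3 barcodes; `barcode_rank()` rejects empty input;
  all-equal read totals give a weak knee, not an arbitrary one.
* Matrix I/O validates on read: ragged rows, duplicate identifiers and
  negative or non-integer entries are rejected with the offending line
  number. The dense DigitalExpression TSV (header `GENE` + barcodes) is the
  canonical dialect; Matrix Market triplet files (+ gene/barcode lists) are
  provided for scale. Round trips are the identity.
* All thresholds use inclusive-keep (≥) semantics; all rankings break ties
  lexicographically by barcode.

## Limitations

The doublet extrapolation assumes random pairing and equal species
detectability; it is a point estimate without an uncertainty interval. The
knee detector returns a single rank even when the curve has multiple bends
(e.g. two cell populations of very different sizes); the `weak` flag covers
only the no-knee case. Ambient contamination is neither modeled nor
subtracted anywhere — EmptyDrops-style ambient inference and model-based
doublet scoring are out of scope. UMI and barcode error *correction* is out
of scope; only diagnostics are provided.
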