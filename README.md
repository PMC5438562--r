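# dropkit

Quality control and exploratory analysis for droplet single-cell RNA-seq
(Drop-seq-style libraries), with a ground-truth simulator that makes every
stage verifiable.

## The problem

In droplet scRNA-seq, each bead carries a 12-base **cell barcode** and a
random 8-base **UMI** per capture oligo (read 1 = barcode + UMI). Cell
loading is Poisson-limited, so most beads (> 95 %) capture only **ambient
RNA** and produce thousands of low-read barcodes. Before any analysis you
must decide which barcodes are cells, collapse PCR duplicates into molecule
counts, and screen for artifacts: doublets, bare nuclei, broken cells,
defective barcodes.

dropkit implements the standard exploratory toolkit around these decisions:

* **Digital counting** — `count_umis()` collapses tagged reads to distinct
  (barcode, UMI, gene) triples: the digital gene expression (DGE) matrix.
* **Knee detection** — `barcode_rank()` orders barcodes by descending reads
  with cumulative fractions; `find_knee()` finds the inflection point as the
  rank *k* maximizing the perpendicular distance between the (smoothed)
  cumulative curve and the chord joining its endpoints.
* **Filtering & QC** — `filter_min_umis()` (presets 3500 / 1000 / 300 UMIs
  for cell lines / fly embryo / mouse brain), `filter_genes_min_count()`,
  `keep_best_cells()`, and `cell_qc()` with the non-mitochondrial content
  `100 · (total − mito) / total` per cell; `flag_low_mito_cells()` marks
  candidate nuclei.
* **Barnyard doublet analysis** — for two-species mixtures,
  `call_species()` applies the 90 % purity rule (purity =
  max(u_a, u_b)/(u_a + u_b), inclusive at the boundary: 90 of 100 UMIs
  declares the species) and `summarize_barnyard()` extrapolates the total
  doublet rate from the observed cross-species fraction *f* as
  *f / (2pq)* for mixing proportions (p, q).
* **Normalization & correlation** — `atpm_normalize()` (average transcripts
  per million: counts / cell total × max cell total), `pseudobulk()`,
  `correlate_profiles()` (Pearson on log2(x+1) over the gene intersection),
  `rpkm()` for bulk comparators using mean isoform lengths.
* **Barcode diagnostics** — `barcode_base_composition()` scores the
  bead-synthesis T-bias at the last barcode base.
* **Simulator** — `sim_params()` / `simulate_run()` / `simulate_dge()` /
  `make_barnyard()` generate runs with ambient-only beads, doublets, PCR
  duplication and barcode corruption, plus a per-barcode truth table.

Results come back as tibbles (with `tidy()` / `glance()` methods) and the
DGE as a sparse `Matrix`; `autoplot()` / `plot_knee()` / `plot_barnyard()` /
`plot_qc_violin()` give the standard figures. See the methods vignette
(`vignettes/droplet-qc-methods.Rmd`) for the model, parameter meanings and
design choices.

## Worked example

A simulated 100-cell human/mouse barnyard against 2000 ambient beads:

```r
library(dropkit)

params <- sim_params(n_cells = 100, n_ambient_barcodes = 2000,
                     doublet_rate = 0.05, seed = 3)
run <- simulate_run(params)
#> <droplet_run> 2100 barcodes (100 cell-containing, 2000 ambient-only)
#>   reads: 2834325 tagged reads

rank <- barcode_rank(run$reads)
knee <- find_knee(rank)
#> <knee_result> 100 cells (sharp knee, 97.9% of reads, chord distance 0.649)

dge   <- count_umis(run$reads)
cells <- select_cells(dge, knee, read_totals = setNames(rank$reads, rank$barcode))
kept  <- filter_min_umis(cells, qc_profile("cell_line")$min_umis)

glance(cell_qc(kept, run$profiles$annotation))
#>   n_cells n_zero_umi median_genes median_umis median_non_mito_percent
#> 1      97          0          921        8344                    90.0

calls <- call_species(species_counts(dge, run$profiles$annotation))
summarize_barnyard(calls)
#> <barnyard_summary>
#>   human: 58  mouse: 37  doublets: 2  below threshold: 2003
#>   cross-species doublet fraction: 0.0206
#>   extrapolated total doublet rate: 0.0412

barcode_base_composition(run$truth$barcode)
#> <base_composition> 12 barcode positions
#>   T-excess at final base: +0.0313
```

Reading the output: the knee lands exactly on the 100 simulated cells
(97.9 % of reads fall on cell barcodes); after the 3500-UMI cell-line filter
97 cells remain with a median of 921 genes and 8344 UMIs each, and the
median non-mitochondrial content of 90 % matches the simulated 10 %
mitochondrial load. Two of the 97 passing barcodes mix human and mouse
transcripts; doubling the cross-species fraction (equal mix) estimates a
4.1 % total doublet rate against the simulated 5 %. The +0.03 T-excess
reflects the simulator's default 5 % barcode-corruption probability
(expected excess 0.05 × 0.75 ≈ 0.04).

A command-line wrapper over the same functions is installed at
`inst/scripts/dropkit` (subcommands `simulate`, `count`, `knee`, `filter`,
`qc`, `barnyard`, `normalize`, `correlate`, `run`), and `run_pipeline()`
executes the whole workflow with one seed, writing every intermediate plus
a machine-readable `summary.json`.

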