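#' Configuration for an end-to-end droplet QC run
#'
#' Binds the sample profile (which fixes the default minimum-UMI threshold:
#' 3500 for cell lines, 1000 for fly embryo, 300 for mouse brain), the
#' analysis thresholds, the output formats and the seed for one
#' [run_pipeline()] execution.
#'
#' @param out_dir Directory for all artifacts (created if absent).
#' @param profile Sample profile, see [qc_profile()].
#' @param min_umis Minimum UMIs per cell; defaults to the profile's value.
#' @param purity_threshold Species purity threshold for [call_species()].
#' @param max_mito_percent Nuclei-flagging cutoff for
#'   [flag_low_mito_cells()].
#' @param format DGE interchange format, `"tsv"` or `"mtx"`.
#' @param seed Master seed; also seeds the simulator unless `sim` is given.
#' @param sim A [sim_params()] object describing the run to simulate, or
#'   `NULL` to analyse an existing read table via the `reads` argument of
#'   [run_pipeline()].
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(out_dir,
                       profile = c("cell_line", "fly_embryo", "mouse_brain"),
                       min_umis = NULL,
                       purity_threshold = 0.90,
                       max_mito_percent = 1,
                       format = c("tsv", "mtx"),
                       seed = 1L,
                       sim = sim_params(seed = seed)) {
  if (length(profile) == 1 && !profile %in% c("cell_line", "fly_embryo", "mouse_brain")) {
    abort(sprintf("Unknown profile '%s'.", profile))
  }
  prof <- qc_profile(match.arg(profile))
  structure(
    list(
      out_dir = out_dir,
      profile = prof$profile,
      min_umis = as.integer(min_umis %||% prof$min_umis),
      purity_threshold = purity_threshold,
      max_mito_percent = max_mito_percent,
      format = match.arg(format),
      seed = as.integer(seed),
      sim = sim
    ),
    class = "run_config"
  )
}

#' Run the droplet QC workflow end to end
#'
#' Executes simulate (or ingest) -> count -> knee -> select -> filter -> QC
#' -> barnyard (two-species runs) -> normalize/pseudobulk, writing every
#' intermediate in its declared format plus a machine-readable
#' `summary.json`. Every stage logs its effective parameters to stderr. The
#' whole run is deterministic under a fixed seed.
#'
#' @param config A [run_config()].
#' @param reads Optional tagged-read tibble to analyse instead of
#'   simulating (the `sim` entry of the config is then ignored); a gene
#'   `annotation` must be supplied with it.
#' @param annotation Gene annotation table, required with `reads`.
#' @return Invisibly, the summary list written to `summary.json`.
#' @export
run_pipeline <- function(config, reads = NULL, annotation = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  log_stage <- function(fmt, ...) message(sprintf(paste0("[dropkit] ", fmt), ...))

  summary <- list(profile = config$profile, min_umis = config$min_umis,
                  purity_threshold = config$purity_threshold,
                  max_mito_percent = config$max_mito_percent, seed = config$seed)

  if (is.null(reads)) {
    log_stage("simulate: n_cells=%d ambient=%d seed=%d",
              config$sim$n_cells, config$sim$n_ambient_barcodes, config$sim$seed)
    run <- simulate_run(config$sim)
    reads <- run$reads
    annotation <- run$profiles$annotation
    write_tagged_reads(reads, out("tagged_reads.tsv"))
    readr::write_tsv(run$truth, out("truth.tsv"))
    write_sim_params(config$sim, out("sim_params.yaml"))
  } else {
    if (is.null(annotation)) abort("`annotation` is required when `reads` are supplied.")
    validate_tagged_reads(reads)
  }
  write_gene_annotation(annotation, out("gene_annotation.tsv"))

  log_stage("count: %d tagged reads", nrow(reads))
  dge <- count_umis(reads)
  dropped <- attr(dge, "dropped")
  write_dge(dge, out(if (config$format == "tsv") "dge.tsv" else "dge"), config$format)
  summary$n_reads <- nrow(reads)
  summary$reads_dropped <- as.list(dropped)

  log_stage("knee: ranking %d barcodes", ncol(dge))
  rank <- barcode_rank(reads)
  knee <- find_knee(rank)
  readr::write_tsv(tidy(knee), out("knee.tsv"))
  comp <- barcode_base_composition(rank)
  summary$knee <- list(n_cells = knee$n_cells,
                       cumulative_fraction = knee$cumulative_fraction_at_knee,
                       confidence = knee$confidence_flag)
  summary$barcode_t_excess <- comp$t_excess

  log_stage("select: keeping top %d barcodes (%s knee)", knee$n_cells, knee$confidence_flag)
  totals <- setNames(rank$reads, rank$barcode)
  sel <- select_cells(dge, knee, read_totals = totals)

  log_stage("filter: min_umis=%d (%s profile)", config$min_umis, config$profile)
  filt <- filter_min_umis(sel, config$min_umis)
  summary$cells_selected <- ncol(sel)
  summary$cells_after_min_umis <- ncol(filt)

  qc <- cell_qc(filt, annotation)
  nuclei <- flag_low_mito_cells(qc, config$max_mito_percent)
  qc_out <- dplyr::mutate(qc, flagged_low_mito = .data$barcode %in% nuclei)
  readr::write_tsv(qc_out, out("cell_qc.tsv"))
  g <- glance(qc)
  summary$qc <- list(median_genes = g$median_genes, median_umis = g$median_umis,
                     median_non_mito_percent = g$median_non_mito_percent,
                     n_flagged_low_mito = length(nuclei))
  log_stage("qc: median genes %.0f, median UMIs %.0f", g$median_genes, g$median_umis)

  species <- sort(unique(annotation$species))
  if (length(species) == 2L && ncol(filt) > 0) {
    log_stage("barnyard: species %s / %s", species[1L], species[2L])
    counts <- species_counts(select_cells(dge, ncol(dge)), annotation)
    calls <- call_species(counts, config$purity_threshold, config$min_umis)
    readr::write_tsv(calls, out("species_calls.tsv"))
    bs <- summarize_barnyard(calls)
    summary$barnyard <- list(
      counts = as.list(bs$counts),
      cross_species_doublet_fraction = bs$cross_species_doublet_fraction,
      extrapolated_total_doublet_rate = bs$extrapolated_total_doublet_rate
    )
  }

  if (ncol(filt) > 0 && sum(filt) > 0) {
    log_stage("normalize: ATPM over %d cells", ncol(filt))
    atpm <- atpm_normalize(filt)
    pb <- pseudobulk(filt)
    readr::write_tsv(tibble(gene = pb$gene, value = pb$value, unit = "raw_counts"),
                     out("pseudobulk.tsv"))
  }

  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  log_stage("done: %s", out("summary.json"))
  invisible(summary)
}
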