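#' Per-barcode species UMI counts in a two-species run
#'
#' In a barnyard experiment, cells from two species are deliberately mixed so
#' that barcodes mixing both species' transcripts reveal cell doublets. This
#' sums each barcode's UMIs within each species' gene set.
#'
#' @param dge Genes x barcodes count matrix from a two-species run.
#' @param annotation Gene annotation with `gene_id` and `species`; every gene
#'   in `dge` must be assigned to exactly one of two species.
#' @return A tibble with columns `barcode`, `umis_a`, `umis_b`; the species
#'   behind `a` and `b` (sorted label order) are recorded in the `species`
#'   attribute.
#' @export
species_counts <- function(dge, annotation) {
  dge <- as_dge(dge)
  sp_of <- setNames(annotation$species, annotation$gene_id)
  unknown <- setdiff(rownames(dge), names(sp_of))
  if (length(unknown) > 0) {
    abort(sprintf("Gene '%s' has no species assignment.", unknown[1L]))
  }
  sp <- sp_of[rownames(dge)]
  labels <- sort(unique(annotation$species))
  if (length(labels) != 2L) {
    abort(sprintf("Species analysis requires exactly two species; annotation has %d.",
                  length(labels)))
  }
  out <- tibble(
    barcode = colnames(dge),
    umis_a = as.integer(colSums(dge[sp == labels[1L], , drop = FALSE])),
    umis_b = as.integer(colSums(dge[sp == labels[2L], , drop = FALSE]))
  )
  attr(out, "species") <- c(a = labels[1L], b = labels[2L])
  out
}

#' Call species identity per barcode (the 90 percent rule)
#'
#' A cell is confidently declared to belong to one species when at least 90
#' percent of its UMIs come from that species' genes (90 out of 100 UMIs is
#' declared — the boundary is inclusive). Mixed barcodes below the purity
#' threshold are doublets, and barcodes with fewer total UMIs than
#' `min_umis` are set aside as `below_threshold` before any species call is
#' attempted.
#'
#' @param counts A [species_counts()] tibble (`barcode`, `umis_a`, `umis_b`).
#' @param purity_threshold Minimum species purity to declare a singlet
#'   (default 0.90).
#' @param min_umis Minimum total UMIs for a call (default 3500, the
#'   cell-line profile; see [qc_profile()]).
#' @return A tibble of class `species_calls` with added columns `total`,
#'   `purity` (`max(umis_a, umis_b) / total`, NA when total is 0) and
#'   `label` in `species_a`/`species_b`/`doublet`/`below_threshold`.
#' @export
#' @examples
#' counts <- tibble::tibble(barcode = c("B1", "B2", "B3"),
#'                          umis_a = c(9000, 3150, 2000),
#'                          umis_b = c(500, 350, 2000))
#' call_species(counts)
call_species <- function(counts, purity_threshold = 0.90, min_umis = 3500) {
  if (!all(c("barcode", "umis_a", "umis_b") %in% names(counts))) {
    abort("`counts` must have columns barcode, umis_a, umis_b.")
  }
  if (purity_threshold < 0.5 || purity_threshold > 1) {
    abort("`purity_threshold` must be in [0.5, 1].")
  }
  if (min_umis < 0) abort("`min_umis` must be non-negative.")
  total <- counts$umis_a + counts$umis_b
  purity <- ifelse(total > 0, pmax(counts$umis_a, counts$umis_b) / total, NA_real_)
  label <- dplyr::case_when(
    total < min_umis ~ "below_threshold",
    purity >= purity_threshold & counts$umis_a >= counts$umis_b ~ "species_a",
    purity >= purity_threshold ~ "species_b",
    .default = "doublet"
  )
  out <- dplyr::mutate(counts, total = total, purity = purity, label = label)
  attr(out, "species") <- attr(counts, "species")
  attr(out, "min_umis") <- min_umis
  attr(out, "purity_threshold") <- purity_threshold
  class(out) <- c("species_calls", class(out))
  out
}

#' Summarize a barnyard run and extrapolate the total doublet rate
#'
#' Counts calls per label and computes the cross-species doublet fraction
#' among barcodes passing the UMI threshold. Same-species doublets are
#' invisible in a barnyard plot, so the observed cross-species fraction is
#' extrapolated to a total doublet rate by the random-pairing correction:
#' with mixing proportions (p, q), a fraction 2pq of doublets is
#' cross-species, hence `total_rate = cross_fraction / (2 p q)` (at an equal
#' mix, twice the observed fraction — the reasoning behind expecting roughly
#' 10-15 percent same-species doublets from a few percent of visible ones).
#'
#' Ambient-derived cross-species UMIs are not subtracted before the purity
#' computation; heavy ambient contamination therefore biases the observed
#' doublet fraction upward.
#'
#' @param calls A [call_species()] tibble.
#' @param mixing_proportions Length-2 numeric, the species mixing
#'   proportions (default an equal mix).
#' @return A list of class `barnyard_summary`: per-label `counts`,
#'   `cross_species_doublet_fraction`, `extrapolated_total_doublet_rate`,
#'   `mixing_proportions` and the thresholds used.
#' @export
summarize_barnyard <- function(calls, mixing_proportions = c(0.5, 0.5)) {
  stopifnot(inherits(calls, "species_calls"))
  if (length(mixing_proportions) != 2L || any(mixing_proportions < 0) ||
      abs(sum(mixing_proportions) - 1) > 1e-8) {
    abort("`mixing_proportions` must be two non-negative values summing to 1.")
  }
  lev <- c("species_a", "species_b", "doublet", "below_threshold")
  n <- table(factor(calls$label, levels = lev))
  n_pass <- sum(n[c("species_a", "species_b", "doublet")])
  if (n_pass == 0) abort("No call passes the UMI threshold; cannot summarize.")
  cross_frac <- as.numeric(n[["doublet"]]) / n_pass
  pq <- prod(mixing_proportions)
  if (pq == 0 && n[["doublet"]] > 0) {
    abort("Observed cross-species doublets but one mixing proportion is 0; inconsistent input.")
  }
  rate <- if (n[["doublet"]] == 0) 0 else cross_frac / (2 * pq)
  structure(
    list(
      counts = setNames(as.integer(n), lev),
      cross_species_doublet_fraction = cross_frac,
      extrapolated_total_doublet_rate = rate,
      mixing_proportions = mixing_proportions,
      min_umis = attr(calls, "min_umis"),
      purity_threshold = attr(calls, "purity_threshold"),
      species = attr(calls, "species")
    ),
    class = "barnyard_summary"
  )
}

#' @export
print.barnyard_summary <- function(x, ...) {
  sp <- x$species %||% c(a = "species_a", b = "species_b")
  cat("<barnyard_summary>\n")
  cat(sprintf("  %s: %d  %s: %d  doublets: %d  below threshold: %d\n",
              sp[["a"]], x$counts[["species_a"]], sp[["b"]], x$counts[["species_b"]],
              x$counts[["doublet"]], x$counts[["below_threshold"]]))
  cat(sprintf("  cross-species doublet fraction: %.4f\n", x$cross_species_doublet_fraction))
  cat(sprintf("  extrapolated total doublet rate: %.4f\n", x$extrapolated_total_doublet_rate))
  invisible(x)
}

#' @rdname summarize_barnyard
#' @param x A `barnyard_summary`.
#' @param ... Unused.
#' @return `tidy()`: one row per label with `label` and `n`. `glance()`: a
#'   one-row tibble with the fractions and thresholds.
#' @method tidy barnyard_summary
#' @export
tidy.barnyard_summary <- function(x, ...) {
  tibble(label = names(x$counts), n = as.integer(x$counts))
}

#' @rdname summarize_barnyard
#' @method glance barnyard_summary
#' @export
glance.barnyard_summary <- function(x, ...) {
  tibble(
    n_species_a = x$counts[["species_a"]],
    n_species_b = x$counts[["species_b"]],
    n_doublet = x$counts[["doublet"]],
    n_below_threshold = x$counts[["below_threshold"]],
    cross_species_doublet_fraction = x$cross_species_doublet_fraction,
    extrapolated_total_doublet_rate = x$extrapolated_total_doublet_rate,
    min_umis = x$min_umis %||% NA_real_,
    purity_threshold = x$purity_threshold %||% NA_real_
  )
}
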