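#' Per-cell quality metrics
#'
#' For every barcode: the total UMI count, the number of genes detected
#' (genes with at least one UMI) and the non-mitochondrial content. The
#' latter is obtained by summing the UMIs from mitochondrially encoded genes,
#' subtracting that sum from the cell's total UMIs, and dividing by the total
#' — expressed as a percentage. Stressed or broken cells leak cytoplasmic
#' mRNA and show low non-mitochondrial content; bare nuclei show the opposite
#' extreme (near 100, see [flag_low_mito_cells()]).
#'
#' Zero-UMI barcodes get `NA` for the percentage (an undefined ratio) and are
#' excluded from the [glance()] medians rather than raising, since upstream
#' filters may not have run yet.
#'
#' @param dge Genes x barcodes count matrix.
#' @param annotation Gene annotation tibble with `gene_id` and `is_mito`;
#'   every gene in `dge` must be annotated.
#' @return A tibble of class `cell_qc` with columns `barcode`, `total_umis`,
#'   `genes_detected`, `mito_umis`, `non_mito_percent`.
#' @export
#' @examples
#' dge <- Matrix::sparseMatrix(i = c(1, 2), j = c(1, 1), x = c(90, 10),
#'   dimnames = list(c("g1", "MT-1"), "AAAAAAAAAAAA"))
#' ann <- tibble::tibble(gene_id = c("g1", "MT-1"), is_mito = c(FALSE, TRUE))
#' cell_qc(dge, ann)
cell_qc <- function(dge, annotation) {
  dge <- as_dge(dge)
  missing <- setdiff(rownames(dge), annotation$gene_id)
  if (length(missing) > 0) {
    abort(sprintf("Gene '%s' is not annotated (and %d more).",
                  missing[1L], length(missing) - 1L))
  }
  mito_genes <- annotation$gene_id[annotation$is_mito]
  total <- colSums(dge)
  mito <- colSums(dge[rownames(dge) %in% mito_genes, , drop = FALSE])
  out <- tibble(
    barcode = colnames(dge),
    total_umis = as.integer(total),
    genes_detected = as.integer(colSums(dge > 0)),
    mito_umis = as.integer(mito),
    non_mito_percent = unname(ifelse(total > 0, 100 * (total - mito) / total, NA_real_))
  )
  class(out) <- c("cell_qc", class(out))
  out
}

#' @rdname cell_qc
#' @param x A `cell_qc` tibble.
#' @param ... Unused.
#' @return `glance()`: a one-row tibble with the number of cells, median
#'   genes detected, median UMIs and median non-mitochondrial percentage
#'   (medians over barcodes with at least one UMI).
#' @method glance cell_qc
#' @export
glance.cell_qc <- function(x, ...) {
  nz <- x[x$total_umis > 0, ]
  tibble(
    n_cells = nrow(x),
    n_zero_umi = sum(x$total_umis == 0),
    median_genes = median(nz$genes_detected),
    median_umis = median(nz$total_umis),
    median_non_mito_percent = median(nz$non_mito_percent)
  )
}

#' Flag candidate nuclei by mitochondrial underrepresentation
#'
#' Intact cells contribute mitochondrially encoded transcripts; bare nuclei
#' lack substantial mitochondrial expression. Cells whose mitochondrial
#' percentage (`100 - non_mito_percent`) is strictly below
#' `max_mito_percent` are flagged as candidate nuclei. "Substantial" has no
#' canonical cutoff; the default of 1 percent is deliberately conservative
#' and is surfaced in every report.
#'
#' @param qc A [cell_qc()] tibble.
#' @param max_mito_percent Mitochondrial-percent cutoff in \[0, 100\].
#' @return Character vector of flagged barcodes.
#' @export
flag_low_mito_cells <- function(qc, max_mito_percent = 1) {
  if (max_mito_percent < 0 || max_mito_percent > 100) {
    abort("`max_mito_percent` must be in [0, 100].")
  }
  mito_pct <- 100 - qc$non_mito_percent
  qc$barcode[!is.na(mito_pct) & mito_pct < max_mito_percent]
}

#' Per-sample QC profiles and their UMI thresholds
#'
#' Binds the default minimum-UMI threshold to the kind of sample being
#' processed: 3500 for cultured cell lines (e.g. HEK/3T3 barnyards), 1000
#' for fly embryo cells, 300 for mouse brain cells. All defaults are
#' overridable at call sites.
#'
#' @param profile One of `"cell_line"`, `"fly_embryo"`, `"mouse_brain"`.
#' @return A list with elements `profile` and `min_umis`.
#' @export
qc_profile <- function(profile = c("cell_line", "fly_embryo", "mouse_brain")) {
  profile <- match.arg(profile)
  list(
    profile = profile,
    min_umis = switch(profile, cell_line = 3500L, fly_embryo = 1000L, mouse_brain = 300L)
  )
}
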