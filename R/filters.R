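#' Remove cells with few UMIs
#'
#' Discards barcodes whose total UMI count is strictly below `min_umis`; a
#' cell sitting exactly at the threshold is kept ("fewer than" semantics —
#' boundary cells exist in practice, so the rule is documented as strict).
#' Typical thresholds by sample type: 3500 (cultured cell lines), 1000 (fly
#' embryo), 300 (mouse brain); see [qc_profile()].
#'
#' @param dge Genes x barcodes count matrix.
#' @param min_umis Non-negative UMI threshold.
#' @return The column-filtered DGE matrix.
#' @seealso [filter_genes_min_count()], [keep_best_cells()]
#' @export
filter_min_umis <- function(dge, min_umis) {
  dge <- as_dge(dge)
  if (min_umis < 0) abort("`min_umis` must be non-negative.")
  dge[, colSums(dge) >= min_umis, drop = FALSE]
}

#' Remove genes with low total counts
#'
#' Drops genes whose total UMI count across the retained cells is strictly
#' below `min_total` (same strict-threshold semantics as
#' [filter_min_umis()]).
#'
#' @param dge Genes x barcodes count matrix.
#' @param min_total Non-negative count threshold.
#' @return The row-filtered DGE matrix.
#' @export
filter_genes_min_count <- function(dge, min_total) {
  dge <- as_dge(dge)
  if (min_total < 0) abort("`min_total` must be non-negative.")
  dge[rowSums(dge) >= min_total, , drop = FALSE]
}

#' Keep the best cells by a quality criterion
#'
#' Retains the `n` highest-ranking cells, by total UMIs (default) or by the
#' number of genes detected. Ties are broken lexicographically by barcode;
#' column order of the survivors is preserved.
#'
#' @param dge Genes x barcodes count matrix.
#' @param n Number of cells to keep (1 to `ncol(dge)`).
#' @param criterion `"umis"` (total UMI count) or `"genes"` (genes with at
#'   least one UMI).
#' @return The column-subset DGE matrix.
#' @export
keep_best_cells <- function(dge, n, criterion = c("umis", "genes")) {
  dge <- as_dge(dge)
  criterion <- match.arg(criterion)
  if (n < 1 || n > ncol(dge)) {
    abort(sprintf("`n` must be between 1 and %d.", ncol(dge)))
  }
  crit <- switch(criterion, umis = colSums(dge), genes = colSums(dge > 0))
  keep <- order(-crit, colnames(dge))[seq_len(n)]
  dge[, sort(keep), drop = FALSE]
}
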