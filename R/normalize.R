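#' ATPM normalization (average transcripts per million)
#'
#' Rescales each cell so all cells have a common total: the UMI counts for
#' every gene in a cell are divided by the sum of all UMIs in that cell, then
#' multiplied by the total of the cell with the highest number of UMIs in the
#' library. A single-cell matrix is therefore a fixed point. Cells with zero
#' total UMIs have no defined scale factor; they are excluded from the output
#' with a warning rather than producing undefined columns.
#'
#' @param dge Genes x barcodes count matrix with at least one non-empty cell.
#' @return A sparse matrix of ATPM values (unit recorded in the `unit`
#'   attribute); every column sums to the maximum raw cell total.
#' @export
atpm_normalize <- function(dge) {
  dge <- as_dge(dge)
  totals <- colSums(dge)
  if (all(totals == 0)) abort("All cells have zero UMIs; nothing to normalize.")
  if (any(totals == 0)) {
    warn(sprintf("Excluding %d zero-UMI cell(s) from ATPM normalization.", sum(totals == 0)))
    dge <- dge[, totals > 0, drop = FALSE]
    totals <- totals[totals > 0]
  }
  out <- dge %*% Diagonal(x = max(totals) / totals)
  dimnames(out) <- dimnames(dge)
  out <- as(out, "CsparseMatrix")
  attr(out, "unit") <- "ATPM"
  out
}

#' Aggregate a DGE matrix into a pseudobulk expression profile
#'
#' Sums gene counts across all cells in the library, producing the aggregate
#' profile used for cross-sample and single-cell-versus-bulk correlations.
#'
#' @param dge Genes x barcodes count matrix with at least one cell.
#' @return A tibble of class `expression_profile` with columns `gene` and
#'   `value`; the unit (`"raw_counts"`) is recorded in the `unit` attribute.
#' @export
pseudobulk <- function(dge) {
  dge <- as_dge(dge)
  if (ncol(dge) == 0) abort("`dge` has no cells.")
  new_expression_profile(rowSums(dge), "raw_counts")
}

new_expression_profile <- function(values, unit) {
  stopifnot(!is.null(names(values)))
  if (any(!is.finite(values)) || (unit != "log2p1" && any(values < 0))) {
    abort("Expression values must be finite (and non-negative for non-log units).")
  }
  out <- tibble(gene = names(values), value = as.numeric(values))
  attr(out, "unit") <- unit
  class(out) <- c("expression_profile", class(out))
  out
}

profile_values <- function(x, arg = "profile") {
  if (inherits(x, "expression_profile") ||
      (is.data.frame(x) && all(c("gene", "value") %in% names(x)))) {
    return(setNames(x$value, x$gene))
  }
  if (is.numeric(x) && !is.null(names(x))) return(x)
  abort(sprintf("`%s` must be an expression profile (gene/value table or named vector).", arg))
}

#' Convert bulk counts to RPKM
#'
#' Reads per kilobase of transcript per million mapped reads, using as gene
#' length the pre-computed mean over all of the gene's isoform lengths from
#' the annotation table:
#' `count / (length_bp / 1000) / (total_mapped_reads / 1e6)`.
#'
#' @param bulk_counts Expression profile of raw counts (gene/value tibble or
#'   named vector).
#' @param annotation Gene annotation with `gene_id` and
#'   `mean_isoform_length` (bp, positive) covering every gene in the
#'   profile.
#' @param total_mapped_reads Positive library size used for the
#'   per-million scaling.
#' @return An `expression_profile` in RPKM units.
#' @export
#' @examples
#' ann <- tibble::tibble(gene_id = "g1", species = "human",
#'                       is_mito = FALSE, mean_isoform_length = 1000)
#' rpkm(c(g1 = 1), ann, total_mapped_reads = 1e6) # 1 RPKM
rpkm <- function(bulk_counts, annotation, total_mapped_reads) {
  v <- profile_values(bulk_counts, "bulk_counts")
  if (total_mapped_reads <= 0) abort("`total_mapped_reads` must be positive.")
  len <- setNames(annotation$mean_isoform_length, annotation$gene_id)
  missing <- setdiff(names(v), names(len)[!is.na(len)])
  if (length(missing) > 0) {
    abort(sprintf("Gene '%s' has no mean isoform length in the annotation.", missing[1L]))
  }
  l <- len[names(v)]
  if (any(l <= 0)) abort("Mean isoform lengths must be positive.")
  new_expression_profile(v / (l / 1000) / (total_mapped_reads / 1e6), "RPKM")
}

#' Correlate two expression profiles in log space
#'
#' Subsets both profiles to the intersection of the genes captured in both
#' libraries, applies `log2(value + 1)` and computes the Pearson
#' correlation. The intersection size is reported alongside the coefficient,
#' since a small common gene set undermines the comparison.
#'
#' @param profile_x,profile_y Expression profiles (gene/value tibbles or
#'   named vectors); units need not match (each is transformed
#'   independently).
#' @param transform Transformation applied to both profiles before the
#'   correlation (default `log2(x + 1)`).
#' @return A one-row tibble with `estimate` (Pearson r) and
#'   `n_common_genes`.
#' @export
correlate_profiles <- function(profile_x, profile_y, transform = function(v) log2(v + 1)) {
  x <- profile_values(profile_x, "profile_x")
  y <- profile_values(profile_y, "profile_y")
  common <- intersect(names(x), names(y))
  if (length(common) == 0) {
    abort("The two profiles share no genes; correlation is undefined.")
  }
  tx <- unname(transform(x[common]))
  ty <- unname(transform(y[common]))
  if (length(common) < 3 || stats::sd(tx) == 0 || stats::sd(ty) == 0) {
    abort("Need at least 3 common genes with non-zero variance in both profiles.")
  }
  # a profile against itself is 1 by definition; bypass rounding in cor()
  r <- if (identical(tx, ty)) 1 else cor(tx, ty, method = "pearson")
  tibble(estimate = r, n_common_genes = length(common))
}

#' Pairwise correlation matrix across samples
#'
#' Applies [correlate_profiles()] to every pair of pseudobulk profiles.
#'
#' @param profiles Named list of expression profiles.
#' @inheritParams correlate_profiles
#' @return A tibble with columns `sample_x`, `sample_y`, `estimate`,
#'   `n_common_genes`, one row per unordered pair (including the diagonal).
#' @export
correlate_samples <- function(profiles, transform = function(v) log2(v + 1)) {
  stopifnot(is.list(profiles), !is.null(names(profiles)))
  nm <- names(profiles)
  pairs <- which(upper.tri(diag(length(nm)), diag = TRUE), arr.ind = TRUE)
  purrr::map_dfr(seq_len(nrow(pairs)), function(k) {
    i <- pairs[k, 1L]; j <- pairs[k, 2L]
    r <- correlate_profiles(profiles[[i]], profiles[[j]], transform)
    dplyr::mutate(r, sample_x = nm[i], sample_y = nm[j], .before = 1L)
  })
}
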