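#' Find the knee of a barcode-rank curve
#'
#' Cell numbers in a droplet run are selected from the inflection point
#' ("knee") of the cumulative read distribution: barcodes are ordered by
#' descending reads, the cumulative fraction of reads is plotted against
#' rank, and barcodes beyond the knee are taken to carry only ambient RNA.
#'
#' The knee is computed deterministically and parameter-free: ranks are
#' rescaled to \[0, 1\], the cumulative fraction is median-smoothed
#' (running median, default window 5; a no-op wherever the curve is
#' monotone), and the knee is the rank maximizing the perpendicular distance
#' between the curve and the chord joining its first and last points. When
#' that maximum distance is small the curve is close to a straight line — no
#' real cell/ambient separation — and the result is flagged `weak`.
#'
#' @param table A [barcode_rank()] tibble with at least 3 barcodes.
#' @param smooth_window Odd window for the running median (default 5).
#' @param weak_threshold Maximum chord distance below which the knee is
#'   flagged `weak` (default 0.05).
#' @return A list of class `knee_result`: `n_cells` (rank of the knee),
#'   `cumulative_fraction_at_knee`, `confidence_flag` (`"sharp"` or
#'   `"weak"`) and `max_distance`.
#' @export
#' @examples
#' rk <- barcode_rank(c(setNames(rep(1000, 20), sprintf("C%02d", 1:20)),
#'                      setNames(rep(2, 200), sprintf("A%03d", 1:200))))
#' find_knee(rk)
find_knee <- function(table, smooth_window = 5L, weak_threshold = 0.05) {
  if (!is.data.frame(table) || !all(c("rank", "cumulative_fraction") %in% names(table))) {
    abort("`table` must be a barcode_rank table.")
  }
  n <- nrow(table)
  if (n < 3) abort("Knee detection needs at least 3 barcodes.")
  w <- min(smooth_window, if (n %% 2 == 0) n - 1L else n)
  x <- (table$rank - 1) / (n - 1)
  y <- stats::runmed(table$cumulative_fraction, w, endrule = "keep")
  # perpendicular distance from each point to the chord (x1,y1)-(xn,yn)
  dx <- x[n] - x[1L]
  dy <- y[n] - y[1L]
  d <- abs((y - y[1L]) * dx - (x - x[1L]) * dy) / sqrt(dx^2 + dy^2)
  k <- which.max(d)
  structure(
    list(
      n_cells = as.integer(table$rank[k]),
      cumulative_fraction_at_knee = table$cumulative_fraction[k],
      confidence_flag = if (d[k] < weak_threshold) "weak" else "sharp",
      max_distance = d[k]
    ),
    class = "knee_result"
  )
}

#' @export
print.knee_result <- function(x, ...) {
  cat(sprintf(
    "<knee_result> %d cells (%s knee, %.1f%% of reads, chord distance %.3f)\n",
    x$n_cells, x$confidence_flag, 100 * x$cumulative_fraction_at_knee, x$max_distance
  ))
  invisible(x)
}

#' @rdname find_knee
#' @param x A `knee_result`.
#' @param ... Unused.
#' @return `tidy()` / `glance()`: a one-row tibble with columns `n_cells`,
#'   `cumulative_fraction_at_knee`, `confidence_flag`, `max_distance`.
#' @method tidy knee_result
#' @export
tidy.knee_result <- function(x, ...) {
  tibble(
    n_cells = x$n_cells,
    cumulative_fraction_at_knee = x$cumulative_fraction_at_knee,
    confidence_flag = x$confidence_flag,
    max_distance = x$max_distance
  )
}

#' @rdname find_knee
#' @method glance knee_result
#' @export
glance.knee_result <- function(x, ...) tidy(x)

#' Keep the top barcodes of a DGE matrix
#'
#' Retains the `n` barcodes with the largest read totals — or, when read
#' totals are not supplied, the largest UMI totals — matching the number of
#' single-cell transcriptomes expected from the run (typically the
#' [find_knee()] estimate). Column order of the retained barcodes is
#' preserved; ties at the boundary are broken lexicographically by barcode.
#'
#' @param dge Genes x barcodes count matrix.
#' @param n Number of barcodes to keep, or a `knee_result`.
#' @param read_totals Optional named per-barcode read totals to rank by.
#' @return The column-subset DGE matrix.
#' @export
select_cells <- function(dge, n, read_totals = NULL) {
  dge <- as_dge(dge)
  if (inherits(n, "knee_result")) n <- n$n_cells
  if (n <= 0) abort("`n` must be positive.")
  if (n > ncol(dge)) abort(sprintf("`n` (%d) exceeds the %d barcodes present.", n, ncol(dge)))
  crit <- if (!is.null(read_totals)) {
    if (is.null(names(read_totals)) || !all(colnames(dge) %in% names(read_totals))) {
      abort("`read_totals` must be named and cover every barcode in `dge`.")
    }
    as.numeric(read_totals[colnames(dge)])
  } else {
    colSums(dge)
  }
  keep <- order(-crit, colnames(dge))[seq_len(n)]
  dge[, sort(keep), drop = FALSE]
}
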