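#' Knee plot of a barcode-rank table
#'
#' Cumulative fraction of reads against barcodes ordered by descending read
#' count, optionally with the detected knee marked.
#'
#' @param object A [barcode_rank()] tibble.
#' @param knee Optional [find_knee()] result to mark.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot barcode_rank
#' @export
autoplot.barcode_rank <- function(object, knee = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$rank, y = .data$cumulative_fraction)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Cell barcodes (by descending reads)",
                  y = "Cumulative fraction of reads") +
    ggplot2::theme_classic()
  if (!is.null(knee)) {
    p <- p + ggplot2::geom_vline(xintercept = knee$n_cells, colour = "red",
                                 linetype = "dashed")
  }
  p
}

#' @rdname autoplot.barcode_rank
#' @param rank_table A [barcode_rank()] tibble.
#' @export
plot_knee <- function(rank_table, knee = NULL) autoplot(rank_table, knee = knee)

#' Species-separation scatter plot of a barnyard run
#'
#' Each barcode is placed by its UMI counts in the two species' gene sets
#' and coloured by its call: pure cells hug the axes, doublets sit off the
#' diagonal, and barcodes below the UMI threshold are grey.
#'
#' @param object A [call_species()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot species_calls
#' @export
autoplot.species_calls <- function(object, ...) {
  sp <- attr(object, "species") %||% c(a = "species A", b = "species B")
  cols <- c(species_a = "#1f77b4", species_b = "#d62728",
            doublet = "#9467bd", below_threshold = "grey70")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$umis_a, y = .data$umis_b,
                                       colour = .data$label)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.8) +
    ggplot2::scale_colour_manual(values = cols) +
    ggplot2::labs(x = sprintf("%s UMIs", sp[["a"]]), y = sprintf("%s UMIs", sp[["b"]]),
                  colour = NULL) +
    ggplot2::theme_classic()
}

#' @rdname autoplot.species_calls
#' @param calls A [call_species()] tibble.
#' @export
plot_barnyard <- function(calls) autoplot(calls)

#' Violin plots of per-cell QC metrics
#'
#' Distributions of genes detected and total UMIs per cell (log scale), the
#' standard per-sample quality view.
#'
#' @param object A [cell_qc()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cell_qc
#' @export
autoplot.cell_qc <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object[object$total_umis > 0, c("barcode", "total_umis", "genes_detected")],
    cols = c("total_umis", "genes_detected"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::stat_summary(fun = median, geom = "point", size = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "Per-cell count (log scale)") +
    ggplot2::theme_classic()
}

#' @rdname autoplot.cell_qc
#' @param qc A [cell_qc()] tibble.
#' @export
plot_qc_violin <- function(qc) autoplot(qc)
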