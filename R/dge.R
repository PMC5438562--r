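#' Split read-1 sequences into cell barcode and UMI
#'
#' Read 1 of a droplet library is a 20-mer: bases 1-12 are the cell barcode
#' and bases 13-20 the unique molecular identifier (UMI). Reads containing an
#' N anywhere are flagged invalid (and are dropped by [count_umis()]); base
#' qualities are not modelled.
#'
#' @param sequence Character vector of 20-base read-1 sequences over
#'   \{A,C,G,T,N\}.
#' @return A tibble with columns `barcode` (12-mer), `umi` (8-mer) and
#'   `valid` (FALSE when the read contains an N).
#' @export
#' @examples
#' parse_read1("ACGTACGTACGTAAAAGGGG")
parse_read1 <- function(sequence) {
  len <- nchar(sequence)
  if (any(len != BARCODE_LENGTH + UMI_LENGTH)) {
    bad <- which(len != BARCODE_LENGTH + UMI_LENGTH)[1L]
    abort(sprintf(
      "Read 1 must be %d bases (12 barcode + 8 UMI); sequence %d has length %d.",
      BARCODE_LENGTH + UMI_LENGTH, bad, len[bad]
    ))
  }
  if (any(grepl("[^ACGTN]", sequence))) {
    abort("Read 1 sequences may only contain A, C, G, T or N.")
  }
  tibble(
    barcode = substr(sequence, 1L, BARCODE_LENGTH),
    umi = substr(sequence, BARCODE_LENGTH + 1L, BARCODE_LENGTH + UMI_LENGTH),
    valid = !grepl("N", sequence, fixed = TRUE)
  )
}

validate_tagged_reads <- function(reads) {
  req <- c("barcode", "umi", "gene")
  if (!is.data.frame(reads) || !all(req %in% names(reads))) {
    abort("`reads` must be a data frame with columns barcode, umi and gene.")
  }
  reads
}

# Well-formedness mask for tagged reads; malformed reads are skipped by
# count_umis and tallied rather than raising.
tagged_read_ok <- function(reads) {
  !is.na(reads$barcode) & !is.na(reads$umi) &
    nchar(reads$barcode) == BARCODE_LENGTH & nchar(reads$umi) == UMI_LENGTH &
    !grepl("[^ACGT]", reads$barcode) & !grepl("[^ACGT]", reads$umi)
}

#' Digital UMI counting: collapse tagged reads into a DGE matrix
#'
#' PCR amplifies each captured molecule into many reads; the UMI identifies
#' the molecule, so counting distinct UMIs per (cell barcode, gene) removes
#' the duplicates and digitally counts mRNA molecules. Collapse is by exact
#' UMI string match; single-mismatch merging is deliberately out of scope.
#'
#' Reads without a gene label, or with a malformed barcode/UMI (wrong length,
#' characters outside ACGT, N from low-quality cycles), are skipped and
#' tallied in the `dropped` attribute of the result.
#'
#' @param reads Tibble of tagged reads with columns `barcode`, `umi`, `gene`
#'   (`gene` may be `NA` for unassigned reads).
#' @return A sparse genes x barcodes matrix (`dgCMatrix`) of distinct-UMI
#'   counts, rows and columns sorted lexicographically, with an attribute
#'   `dropped` = c(no_gene = ..., malformed = ...).
#' @export
count_umis <- function(reads) {
  validate_tagged_reads(reads)
  if (nrow(reads) == 0) {
    out <- sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                        dims = c(0L, 0L), dimnames = list(character(0), character(0)))
    attr(out, "dropped") <- c(no_gene = 0L, malformed = 0L)
    return(out)
  }
  no_gene <- is.na(reads$gene) | !nzchar(reads$gene)
  ok <- tagged_read_ok(reads)
  keep <- ok & !no_gene
  dropped <- c(no_gene = sum(no_gene & ok), malformed = sum(!ok))

  mol <- dplyr::distinct(reads[keep, c("barcode", "umi", "gene")])
  genes <- sort(unique(mol$gene))
  bcs <- sort(unique(mol$barcode))
  out <- sparseMatrix(
    i = match(mol$gene, genes), j = match(mol$barcode, bcs), x = 1,
    dims = c(length(genes), length(bcs)), dimnames = list(genes, bcs)
  )
  attr(out, "dropped") <- dropped
  out
}

#' Rank barcodes by read count and accumulate read fractions
#'
#' The substrate of the knee plot: barcodes ordered by descending number of
#' reads, with the cumulative fraction of all reads at each rank. Most beads
#' see only ambient RNA, so the curve rises steeply over the cell-containing
#' barcodes and then flattens; the inflection point marks the number of cells
#' (see [find_knee()]).
#'
#' @param x Either a tagged-read tibble (reads are counted per barcode; a
#'   `gene` column is not required), a two-column data frame
#'   (`barcode`, `reads`), or a named numeric vector of per-barcode read
#'   totals.
#' @return A tibble of class `barcode_rank` with columns `rank`, `barcode`,
#'   `reads`, `cumulative_fraction`. Ties in `reads` are broken
#'   lexicographically by barcode.
#' @export
barcode_rank <- function(x) {
  if (is.numeric(x) && !is.null(names(x))) {
    totals <- tibble(barcode = names(x), reads = as.numeric(x))
  } else if (is.data.frame(x) && all(c("barcode", "reads") %in% names(x))) {
    totals <- tibble(barcode = x$barcode, reads = as.numeric(x$reads))
  } else if (is.data.frame(x) && "barcode" %in% names(x)) {
    totals <- dplyr::count(x, .data$barcode, name = "reads")
  } else {
    abort("`x` must be a tagged-read table, a (barcode, reads) table or a named numeric vector.")
  }
  if (nrow(totals) == 0) abort("Cannot rank an empty barcode set.")
  if (anyDuplicated(totals$barcode)) {
    totals <- dplyr::summarise(dplyr::group_by(totals, .data$barcode),
                               reads = sum(.data$reads), .groups = "drop")
  }
  totals <- dplyr::arrange(totals, dplyr::desc(.data$reads), .data$barcode)
  out <- tibble(
    rank = seq_len(nrow(totals)),
    barcode = totals$barcode,
    reads = totals$reads,
    cumulative_fraction = cumsum(totals$reads) / sum(totals$reads)
  )
  class(out) <- c("barcode_rank", class(out))
  out
}

#' Per-position base composition of cell barcodes
#'
#' Diagnoses bead-synthesis errors: defective beads carry a truncated barcode
#' whose final synthesis cycle reads into the oligo-dT stretch, so the last
#' (12th) barcode base shows an excess of T. The T-excess score is
#' `freq(T at position 12) - mean(freq(T at positions 1..11))`; under a
#' per-bead corruption probability p it has expectation `p * (1 - 1/4)`.
#'
#' @param x A character vector of 12-mer barcodes (weighted equally), or a
#'   [barcode_rank()] table (each barcode weighted by its read count).
#' @param weights Optional non-negative per-barcode weights overriding the
#'   default.
#' @return A list of class `base_composition`: `frequencies` (12 x 4 matrix,
#'   positions x bases, rows summing to 1) and `t_excess` (scalar score).
#' @export
barcode_base_composition <- function(x, weights = NULL) {
  if (inherits(x, "barcode_rank") || (is.data.frame(x) && all(c("barcode", "reads") %in% names(x)))) {
    weights <- weights %||% x$reads
    x <- x$barcode
  }
  if (!is.character(x) || length(x) == 0) abort("Need at least one barcode.")
  if (any(nchar(x) != BARCODE_LENGTH)) abort("Barcodes must be 12 bases long.")
  weights <- weights %||% rep(1, length(x))
  if (length(weights) != length(x) || any(weights < 0)) {
    abort("`weights` must be non-negative and match the number of barcodes.")
  }

  freq <- matrix(0, BARCODE_LENGTH, 4L,
                 dimnames = list(position = seq_len(BARCODE_LENGTH), base = DNA_BASES))
  wt <- sum(weights)
  for (pos in seq_len(BARCODE_LENGTH)) {
    b <- substr(x, pos, pos)
    for (base in DNA_BASES) {
      freq[pos, base] <- sum(weights[b == base]) / wt
    }
  }
  t_excess <- freq[BARCODE_LENGTH, "T"] - mean(freq[seq_len(BARCODE_LENGTH - 1L), "T"])
  structure(list(frequencies = freq, t_excess = t_excess), class = "base_composition")
}

#' @export
print.base_composition <- function(x, ...) {
  cat("<base_composition> 12 barcode positions\n")
  cat(sprintf("  T-excess at final base: %+.4f\n", x$t_excess))
  invisible(x)
}

#' @rdname barcode_base_composition
#' @param x A `base_composition` object.
#' @param ... Unused.
#' @return `tidy()`: a tibble with one row per (position, base) and columns
#'   `position`, `base`, `frequency`.
#' @method tidy base_composition
#' @export
tidy.base_composition <- function(x, ...) {
  f <- x$frequencies
  tidyr::pivot_longer(
    dplyr::mutate(as_tibble(f), position = seq_len(nrow(f))),
    cols = dplyr::all_of(DNA_BASES), names_to = "base", values_to = "frequency"
  )[, c("position", "base", "frequency")]
}
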