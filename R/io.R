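#' Read and write digital gene expression matrices
#'
#' Two interchange dialects are supported. `"tsv"` is the dense
#' DigitalExpression convention: a tab-separated table whose header row is
#' `GENE` followed by the cell barcodes, one gene per row. `"mtx"` is the
#' sparse triplet convention: a Matrix Market coordinate file `<path>.mtx`
#' with gene identifiers in `<path>.genes.txt` and barcodes in
#' `<path>.barcodes.txt` (one per line). Both round-trip losslessly.
#'
#' @param path File path. For `"mtx"`, the stem: the three component files
#'   get suffixes `.mtx`, `.genes.txt`, `.barcodes.txt`.
#' @param format `"tsv"` (dense, canonical) or `"mtx"` (sparse triplet).
#' @return `read_dge()` returns a sparse genes x barcodes `dgCMatrix`;
#'   `write_dge()` returns `path` invisibly.
#' @export
read_dge <- function(path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (format == "tsv") read_dge_tsv(path) else read_dge_mtx(path)
}

#' @rdname read_dge
#' @param dge A genes x barcodes count matrix (dense or sparse) with
#'   dimnames; entries must be non-negative integers.
#' @export
write_dge <- function(dge, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  dge <- as_dge(dge)
  check_integer_counts(dge@x, "dge")
  if (format == "tsv") {
    df <- as.data.frame(as.matrix(dge), check.names = FALSE)
    df <- cbind(GENE = rownames(dge), df)
    readr::write_tsv(df, path)
  } else {
    Matrix::writeMM(dge, paste0(path, ".mtx"))
    writeLines(rownames(dge), paste0(path, ".genes.txt"))
    writeLines(colnames(dge), paste0(path, ".barcodes.txt"))
  }
  invisible(path)
}

check_integer_counts <- function(v, what, lines = NULL) {
  bad <- !is.finite(v) | v < 0 | v != round(v)
  if (any(bad)) {
    where <- if (!is.null(lines)) sprintf(" (line %d)", lines[which(bad)[1L]]) else ""
    abort(sprintf("`%s` must contain non-negative integer counts%s.", what, where))
  }
  invisible(v)
}

read_dge_tsv <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) abort(sprintf("'%s' is empty.", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  if (header[1L] != "GENE") {
    abort(sprintf("'%s' line 1: dense DGE header must start with 'GENE'.", path))
  }
  bcs <- header[-1L]
  if (anyDuplicated(bcs)) {
    abort(sprintf("'%s': duplicate cell barcode '%s' in header.", path, bcs[duplicated(bcs)][1L]))
  }
  width <- length(header)
  body <- fields[-1L]
  ragged <- which(lengths(body) != width)
  if (length(ragged) > 0) {
    abort(sprintf("'%s' line %d: expected %d fields, found %d.",
                  path, ragged[1L] + 1L, width, lengths(body)[ragged[1L]]))
  }
  genes <- vapply(body, `[`, character(1), 1L)
  if (anyDuplicated(genes)) {
    dup <- genes[duplicated(genes)][1L]
    abort(sprintf("'%s' line %d: duplicate gene row '%s'.",
                  path, which(genes == dup)[2L] + 1L, dup))
  }
  vals <- suppressWarnings(vapply(body, function(f) as.numeric(f[-1L]), numeric(width - 1L)))
  vals <- matrix(vals, nrow = width - 1L) # genes in columns here
  for (i in seq_along(body)) {
    check_integer_counts(vals[, i], "counts", lines = rep(i + 1L, width - 1L))
  }
  m <- Matrix::t(Matrix::Matrix(vals, sparse = TRUE))
  dimnames(m) <- list(genes, bcs)
  as_dge(m)
}

read_dge_mtx <- function(path) {
  m <- as(Matrix::readMM(paste0(path, ".mtx")), "CsparseMatrix")
  genes <- readLines(paste0(path, ".genes.txt"))
  bcs <- readLines(paste0(path, ".barcodes.txt"))
  if (nrow(m) != length(genes) || ncol(m) != length(bcs)) {
    abort(sprintf("'%s': matrix is %d x %d but %d genes / %d barcodes listed.",
                  path, nrow(m), ncol(m), length(genes), length(bcs)))
  }
  if (anyDuplicated(genes)) {
    abort(sprintf("'%s.genes.txt': duplicate gene '%s'.", path, genes[duplicated(genes)][1L]))
  }
  check_integer_counts(m@x, "counts")
  dimnames(m) <- list(genes, bcs)
  as_dge(m)
}

#' Read and write tagged-read tables
#'
#' Tab-separated with columns `barcode`, `umi`, `gene`; an empty `gene` field
#' marks a read that was not assigned to a gene.
#'
#' @param reads A tagged-read tibble.
#' @param path File path.
#' @return `read_tagged_reads()` returns a tibble with columns `barcode`,
#'   `umi`, `gene` (NA when unassigned).
#' @export
write_tagged_reads <- function(reads, path) {
  validate_tagged_reads(reads)
  readr::write_tsv(reads[, c("barcode", "umi", "gene")], path, na = "")
  invisible(path)
}

#' @rdname write_tagged_reads
#' @export
read_tagged_reads <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = character(), progress = FALSE)
  validate_tagged_reads(out)
  out$gene[!nzchar(out$gene)] <- NA_character_
  out
}

#' Read and write gene annotation tables
#'
#' Tab-separated with columns `gene_id`, `species`, `is_mito` (TRUE/FALSE)
#' and `mean_isoform_length` (bp; the mean over all isoforms of the gene,
#' used by [rpkm()]).
#'
#' @param annotation Annotation tibble.
#' @param path File path.
#' @return `read_gene_annotation()` returns the annotation tibble.
#' @export
write_gene_annotation <- function(annotation, path) {
  readr::write_tsv(annotation, path)
  invisible(path)
}

#' @rdname write_gene_annotation
#' @export
read_gene_annotation <- function(path) {
  ann <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), species = readr::col_character(),
    is_mito = readr::col_logical(), mean_isoform_length = readr::col_double()
  ), progress = FALSE)
  if (any(ann$mean_isoform_length <= 0, na.rm = TRUE)) {
    abort("Annotated mean isoform lengths must be positive.")
  }
  ann
}

#' Round-trip simulation parameters through a sidecar config file
#'
#' @param params A [sim_params()] object.
#' @param path YAML file path.
#' @return `read_sim_params()` returns the reconstructed `sim_params`.
#' @export
write_sim_params <- function(params, path) {
  stopifnot(inherits(params, "sim_params"))
  p <- unclass(params)
  p$species_proportions <- as.list(p$species_proportions) # keep names in YAML
  yaml::write_yaml(p, path)
  invisible(path)
}

#' @rdname write_sim_params
#' @export
read_sim_params <- function(path) {
  p <- yaml::read_yaml(path)
  p$species_proportions <- unlist(p$species_proportions)
  do.call(sim_params, p)
}

#' Write simulated read 1 as FASTQ
#'
#' Emits each tagged read as a 20-base read-1 record (bases 1-12 cell
#' barcode, bases 13-20 UMI) with constant quality, carrying the gene label
#' in the header comment.
#'
#' @param reads Tagged-read tibble.
#' @param path Output FASTQ path.
#' @export
write_read1_fastq <- function(reads, path) {
  validate_tagged_reads(reads)
  n <- nrow(reads)
  gene <- ifelse(is.na(reads$gene), "unassigned", reads$gene)
  rec <- character(4L * n)
  rec[seq(1L, by = 4L, length.out = n)] <- sprintf("@read%d gene=%s", seq_len(n), gene)
  rec[seq(2L, by = 4L, length.out = n)] <- paste0(reads$barcode, reads$umi)
  rec[seq(3L, by = 4L, length.out = n)] <- "+"
  rec[seq(4L, by = 4L, length.out = n)] <- strrep("I", BARCODE_LENGTH + UMI_LENGTH)
  writeLines(rec, path)
  invisible(path)
}
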