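DNA_BASES <- c("A", "C", "G", "T")
BARCODE_LENGTH <- 12L
UMI_LENGTH <- 8L
N_UMI_SPACE <- 4L^8L # 65536 distinct 8-mers

# Lookup table mapping integer 1..4^8 to its 8-mer; built lazily, cached per
# session so the simulator can translate UMI indices to strings in one subset.
the <- new.env(parent = emptyenv())

umi_lookup <- function() {
  if (is.null(the$umi_lut)) {
    idx <- arrayInd(seq_len(N_UMI_SPACE), rep(4L, UMI_LENGTH))
    the$umi_lut <- do.call(
      paste0,
      lapply(seq_len(UMI_LENGTH), function(j) DNA_BASES[idx[, j]])
    )
  }
  the$umi_lut
}

random_dna <- function(n, width) {
  m <- matrix(sample(DNA_BASES, n * width, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# n unique random barcodes of BARCODE_LENGTH
random_barcodes <- function(n) {
  bc <- random_dna(n, BARCODE_LENGTH)
  while (anyDuplicated(bc)) {
    d <- duplicated(bc)
    bc[d] <- random_dna(sum(d), BARCODE_LENGTH)
  }
  bc
}

is_count_matrix <- function(x) {
  (is.matrix(x) || is(x, "Matrix")) && !is.null(rownames(x)) && !is.null(colnames(x))
}

as_dge <- function(x, arg = "dge") {
  if (!is_count_matrix(x)) {
    abort(sprintf("`%s` must be a genes x barcodes matrix with dimnames.", arg))
  }
  x <- as(as(x, "CsparseMatrix"), "dMatrix")
  v <- x@x
  if (any(v < 0)) abort(sprintf("`%s` contains negative counts.", arg))
  if (anyDuplicated(rownames(x))) abort(sprintf("`%s` has duplicated gene identifiers.", arg))
  if (anyDuplicated(colnames(x))) abort(sprintf("`%s` has duplicated cell barcodes.", arg))
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
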