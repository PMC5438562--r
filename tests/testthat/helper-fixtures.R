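# Shared fixture builders and independent brute-force oracles.

# genes x cells count matrix with dimnames from a plain matrix
make_dge <- function(mat, genes = NULL, barcodes = NULL) {
  genes <- genes %||% sprintf("g%03d", seq_len(nrow(mat)))
  barcodes <- barcodes %||% random_fixture_barcodes(ncol(mat))
  dimnames(mat) <- list(genes, barcodes)
  methods::as(Matrix::Matrix(mat, sparse = TRUE), "CsparseMatrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic distinct 12-mers (AAA... + base-4 suffix), no RNG involved
random_fixture_barcodes <- function(n) {
  stopifnot(n <= 4^6)
  digits <- arrayInd(seq_len(n), rep(4L, 6L))
  suffix <- apply(digits, 1L, function(d) paste(c("A", "C", "G", "T")[d], collapse = ""))
  paste0("AAAAAA", suffix)
}

random_count_matrix <- function(n_genes, n_cells, lambda = 2, seed = 1) {
  set.seed(seed)
  make_dge(matrix(rpois(n_genes * n_cells, lambda), n_genes, n_cells))
}

# random tagged-read stream with controllable collision pressure
random_read_stream <- function(n_reads, n_barcodes = 20, n_genes = 15, n_umis = 30,
                               seed = 1, na_gene_frac = 0) {
  set.seed(seed)
  gene <- sample(sprintf("g%02d", seq_len(n_genes)), n_reads, replace = TRUE)
  if (na_gene_frac > 0) gene[runif(n_reads) < na_gene_frac] <- NA
  tibble::tibble(
    barcode = sample(random_fixture_barcodes(n_barcodes), n_reads, replace = TRUE),
    umi = sample(substr(random_fixture_barcodes(n_umis), 5L, 12L), n_reads, replace = TRUE),
    gene = gene
  )
}

# oracle: distinct (barcode, umi, gene) triples among well-formed gene-labelled reads
oracle_distinct_triples <- function(reads) {
  keep <- !is.na(reads$gene) & nzchar(reads$gene)
  length(unique(paste(reads$barcode[keep], reads$umi[keep], reads$gene[keep], sep = "\r")))
}

tiny_annotation <- function(dge, mito_genes = character(0), species = "human",
                            lengths = 1000) {
  tibble::tibble(
    gene_id = rownames(dge),
    species = rep_len(species, nrow(dge)),
    is_mito = rownames(dge) %in% mito_genes,
    mean_isoform_length = rep_len(lengths, nrow(dge))
  )
}

# Matrix() returns NULL dimnames on an empty margin; normalize for comparisons
colnames0 <- function(m) colnames(m) %||% character(0)
rownames0 <- function(m) rownames(m) %||% character(0)
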