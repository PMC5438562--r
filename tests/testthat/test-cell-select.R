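test_that("a step distribution puts the knee exactly at the step", {
  totals <- c(setNames(rep(1000, 100), sprintf("CELL%03d", 1:100)),
              setNames(rep(1, 1000), sprintf("AMB%04d", 1:1000)))
  k <- find_knee(barcode_rank(totals))
  expect_equal(k$n_cells, 100L)
  expect_equal(k$confidence_flag, "sharp")
})

test_that("a straight-line cumulative curve yields a weak knee", {
  totals <- setNames(rep(7, 50), sprintf("B%02d", 1:50))
  k <- find_knee(barcode_rank(totals))
  expect_equal(k$confidence_flag, "weak")
  expect_lt(k$max_distance, 0.05)
  expect_error(find_knee(barcode_rank(c(A = 1, B = 2))), "at least 3")
})

test_that("knee recovery on simulated runs lands within 10% of the true cell number", {
  hits <- 0L
  for (s in 1:5) {
    run <- simulate_run(sim_params(
      n_cells = 100, n_ambient_barcodes = 2000,
      library_size_log_mean = log(1000), library_size_log_sd = 0.4,
      reads_per_umi_mean = 2, ambient_reads_mean = 20, seed = 400 + s
    ))
    k <- find_knee(barcode_rank(run$reads))
    if (k$n_cells >= 90 && k$n_cells <= 110) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("select_cells keeps the top barcodes and respects read totals", {
  dge <- make_dge(matrix(c(5, 0, 1, 2, 10, 0), nrow = 2), barcodes = c("B1", "B2", "B3"))
  expect_identical(select_cells(dge, 3), dge)
  expect_equal(colnames(select_cells(dge, 1)), "B3") # highest UMI total
  # with read totals supplied, ranking follows reads, not UMIs
  expect_equal(colnames(select_cells(dge, 1, read_totals = c(B1 = 99, B2 = 1, B3 = 5))), "B1")
  expect_error(select_cells(dge, 0), "positive")
  expect_error(select_cells(dge, 4), "exceeds")

  k <- find_knee(barcode_rank(c(setNames(rep(100, 2), c("B1", "B3")), B2 = 1)))
  expect_s4_class(select_cells(dge, k), "dgCMatrix")
})

test_that("selected cells recover the true cell set on simulated runs", {
  run <- simulate_run(sim_params(
    n_cells = 100, n_ambient_barcodes = 1000,
    library_size_log_mean = log(1000), library_size_log_sd = 0.4,
    reads_per_umi_mean = 2, ambient_reads_mean = 20, seed = 77
  ))
  rk <- barcode_rank(run$reads)
  dge <- count_umis(run$reads)
  sel <- select_cells(dge, find_knee(rk), read_totals = setNames(rk$reads, rk$barcode))
  truth_cells <- run$truth$barcode[run$truth$origin != "ambient_only"]
  jaccard <- length(intersect(colnames(sel), truth_cells)) /
    length(union(colnames(sel), truth_cells))
  expect_gte(jaccard, 0.9)
})

test_that("UMI and gene filters use strict fewer-than semantics", {
  m <- make_dge(matrix(c(3499, 3500, 9000), nrow = 1),
                barcodes = c("B1", "B2", "B3"))
  expect_equal(colnames(filter_min_umis(m, 3500)), c("B2", "B3"))
  expect_identical(filter_min_umis(m, 0), m)

  g <- make_dge(matrix(c(0, 5, 4, 0), nrow = 2), genes = c("g1", "g2"))
  expect_equal(rownames(filter_genes_min_count(g, 5)), "g2") # row totals 4 and 5
  expect_identical(filter_genes_min_count(g, 0), g)
})

test_that("filters agree with the brute-force oracle, including the preset thresholds", {
  set.seed(12)
  m <- make_dge(matrix(rpois(100 * 100, lambda = rep(c(1, 12, 40), length.out = 100)),
                       100, 100))
  dense <- as.matrix(m)
  for (thr in c(0, 1, 10, 300, 1000, 3500)) {
    expect_identical(colnames0(filter_min_umis(m, thr)),
                     colnames(dense)[colSums(dense) >= thr])
    expect_identical(rownames0(filter_genes_min_count(m, thr)),
                     rownames(dense)[rowSums(dense) >= thr])
  }
})

test_that("filters are idempotent and commute", {
  m <- random_count_matrix(60, 40, lambda = 3, seed = 5)
  f1 <- filter_min_umis(m, 150)
  expect_identical(filter_min_umis(f1, 150), f1)
  ab <- filter_genes_min_count(filter_min_umis(m, 150), 100)
  ba <- filter_min_umis(filter_genes_min_count(m, 100), 150)
  # note: commuting holds because each filter recomputes totals on the
  # already-reduced matrix only along its own margin
  expect_identical(as.matrix(ab), as.matrix(ba))
})

test_that("keep_best_cells ranks by criterion with lexicographic ties", {
  m <- make_dge(cbind(c(5, 5), c(10, 0), c(5, 5)), barcodes = c("B3", "B2", "B1"))
  expect_identical(keep_best_cells(m, 3), m)
  kept <- keep_best_cells(m, 2) # B2 (10) then tie B1/B3 -> B1
  expect_setequal(colnames(kept), c("B2", "B1"))
  expect_equal(colnames(keep_best_cells(m, 1, criterion = "genes")), "B1")
  expect_error(keep_best_cells(m, 0), "between 1 and")
  expect_error(keep_best_cells(m, 9), "between 1 and")
})

test_that("non-mitochondrial content follows the subtract-and-divide formula", {
  dge <- make_dge(rbind(c(90, 0, 50), c(10, 0, 0)), genes = c("nuc1", "MT-1"),
                  barcodes = c("B1", "B2", "B3"))
  ann <- tiny_annotation(dge, mito_genes = "MT-1")
  qc <- cell_qc(dge, ann)
  expect_equal(qc$non_mito_percent[qc$barcode == "B1"], 90)
  expect_equal(qc$non_mito_percent[qc$barcode == "B3"], 100)
  expect_true(is.na(qc$non_mito_percent[qc$barcode == "B2"]))
  # conservation: mito + non-mito = total, exactly
  expect_identical(qc$mito_umis + (qc$total_umis - qc$mito_umis), qc$total_umis)

  g <- glance(qc)
  expect_equal(g$n_zero_umi, 1L)
  expect_equal(g$median_umis, 75) # median over the two non-empty cells

  expect_error(cell_qc(dge, ann[-1, ]), "not annotated")
})

test_that("per-cell QC conserves totals on simulated data", {
  run <- simulate_dge(sim_params(n_cells = 50, n_ambient_barcodes = 100,
                                 library_size_log_mean = log(500), seed = 21))
  qc <- cell_qc(run$dge, run$profiles$annotation)
  expect_true(all(qc$mito_umis + (qc$total_umis - qc$mito_umis) == qc$total_umis))
  # median non-mito content reflects the generative 10% mitochondrial load
  cells <- qc[qc$barcode %in% run$truth$barcode[run$truth$origin != "ambient_only"], ]
  expect_lt(abs(median(cells$non_mito_percent) - 90), 2)
})

test_that("nuclei flagging catches mitochondria-free cells", {
  dge <- make_dge(rbind(c(100, 100, 100), c(0, 5, 1)), genes = c("nuc1", "MT-1"),
                  barcodes = c("NUC", "CELL", "LOW"))
  qc <- cell_qc(dge, tiny_annotation(dge, mito_genes = "MT-1"))
  expect_identical(flag_low_mito_cells(qc, 0), character(0))
  expect_setequal(flag_low_mito_cells(qc, 1), c("NUC", "LOW"))

  # simulated nuclei subpopulation: zero out mitochondrial rows for some cells
  run <- simulate_dge(sim_params(n_cells = 60, n_ambient_barcodes = 0,
                                 library_size_log_mean = log(1000), seed = 31))
  dge2 <- run$dge
  ann <- run$profiles$annotation
  nuclei <- colnames(dge2)[1:20]
  dge2[ann$gene_id[ann$is_mito], nuclei] <- 0
  flagged <- flag_low_mito_cells(cell_qc(dge2, ann), 1)
  recall <- length(intersect(flagged, nuclei)) / length(nuclei)
  expect_gte(recall, 0.95)
})

test_that("profiles bind the documented UMI thresholds", {
  expect_equal(qc_profile("cell_line")$min_umis, 3500L)
  expect_equal(qc_profile("fly_embryo")$min_umis, 1000L)
  expect_equal(qc_profile("mouse_brain")$min_umis, 300L)
  expect_error(qc_profile("yeast"))
})
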