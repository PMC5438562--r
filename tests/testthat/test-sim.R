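small_params <- function(...) {
  defaults <- list(
    n_cells = 40, n_ambient_barcodes = 300,
    library_size_log_mean = log(500), library_size_log_sd = 0.4,
    reads_per_umi_mean = 2, ambient_reads_mean = 10, seed = 11
  )
  do.call(sim_params, utils::modifyList(defaults, list(...)))
}

test_that("sim_params validates fractions, counts and dispersion", {
  expect_error(sim_params(doublet_rate = 1.5), "0, 1")
  expect_error(sim_params(species_proportions = c(human = 0.6, mouse = 0.6)), "sum to 1")
  expect_error(sim_params(species_proportions = c(0.5, 0.5)), "named")
  expect_error(sim_params(n_cells = -1), "non-negative")
  expect_error(sim_params(reads_per_umi_mean = 0.5), ">= 1")
  expect_error(sim_params(expression_profile_dispersion = Inf), "finite")
})

test_that("expression profiles are normalized, mito mass is exact, zero dispersion is flat", {
  p <- small_params()
  prof <- simulate_expression_profiles(p)
  for (v in prof$profiles) expect_equal(sum(v), 1)
  mito <- prof$annotation$is_mito[prof$annotation$species == "human"]
  expect_equal(sum(prof$profiles$human[mito]), p$mito_expression_fraction)

  flat <- simulate_expression_profiles(small_params(expression_profile_dispersion = 0))
  non_mito <- flat$profiles$human[!mito]
  expect_true(all(abs(non_mito - non_mito[1]) < 1e-12))

  expect_identical(simulate_expression_profiles(p), simulate_expression_profiles(p))
})

test_that("simulate_run is deterministic and conserves molecules exactly", {
  p <- small_params()
  r1 <- simulate_run(p)
  r2 <- simulate_run(p)
  expect_identical(r1$reads, r2$reads)
  expect_identical(r1$truth, r2$truth)

  # every (barcode, UMI, gene) triple in the stream is one true molecule
  expect_identical(oracle_distinct_triples(r1$reads), sum(r1$truth$total_umis))
  # PCR inflates reads, never deflates
  expect_gte(nrow(r1$reads), sum(r1$truth$total_umis))
  ratio <- nrow(r1$reads) / sum(r1$truth$total_umis)
  expect_lt(abs(ratio - p$reads_per_umi_mean), 0.1)
})

test_that("origin bookkeeping follows the generative parameters", {
  no_doub <- simulate_run(small_params(doublet_rate = 0))
  expect_false(any(no_doub$truth$origin == "doublet"))
  expect_true(all(is.na(no_doub$truth$species_2)))

  empty <- simulate_run(small_params(n_cells = 0, n_ambient_barcodes = 50))
  expect_true(all(empty$truth$origin == "ambient_only"))
  expect_true(all(is.na(empty$truth$species_1)))

  doub <- simulate_run(small_params(doublet_rate = 0.5, seed = 3))
  tr <- doub$truth[doub$truth$origin == "doublet", ]
  expect_true(all(!is.na(tr$species_1) & !is.na(tr$species_2)))
  expect_false(anyDuplicated(doub$truth$barcode) > 0)
})

test_that("cross-species doublets appear at the expected rate", {
  # at an equal mix, half of all doublets pair two different species
  n_doub <- 0L
  n_cross <- 0L
  for (s in 1:10) {
    tr <- simulate_dge(small_params(doublet_rate = 0.2, n_ambient_barcodes = 0,
                                    seed = 100 + s))$truth
    d <- tr[tr$origin == "doublet", ]
    n_doub <- n_doub + nrow(d)
    n_cross <- n_cross + sum(d$species_1 != d$species_2)
  }
  expect_gt(n_doub, 30)
  p_hat <- n_cross / n_doub
  expect_lt(abs(p_hat - 0.5), 3 * sqrt(0.25 / n_doub))
})

test_that("cell draws are insensitive to the size of the ambient pool", {
  a <- simulate_dge(small_params(n_ambient_barcodes = 50))
  b <- simulate_dge(small_params(n_ambient_barcodes = 400))
  cell_a <- a$truth[a$truth$origin != "ambient_only",
                    c("origin", "species_1", "species_2", "total_umis", "mito_umis")]
  cell_b <- b$truth[b$truth$origin != "ambient_only",
                    c("origin", "species_1", "species_2", "total_umis", "mito_umis")]
  expect_identical(cell_a, cell_b)
})

test_that("barnyard wrapper enforces two species and keeps namespaces disjoint", {
  expect_error(make_barnyard(small_params(species_proportions = c(human = 1))),
               "two species")
  run <- make_barnyard(small_params(), level = "dge")
  ann <- run$profiles$annotation
  expect_length(intersect(ann$gene_id[ann$species == "human"],
                          ann$gene_id[ann$species == "mouse"]), 0)

  pure <- make_barnyard(small_params(species_proportions = c(human = 1, mouse = 0)),
                        level = "dge")
  tr <- pure$truth[pure$truth$origin != "ambient_only", ]
  expect_true(all(tr$species_1 == "human"))

  # without doublets or within-bead mixing every cell is >= 99% pure in truth
  nd <- make_barnyard(small_params(doublet_rate = 0), level = "dge")
  counts <- species_counts(nd$dge, nd$profiles$annotation)
  cells <- counts[counts$barcode %in% nd$truth$barcode[nd$truth$origin == "singlet"], ]
  purity <- pmax(cells$umis_a, cells$umis_b) / (cells$umis_a + cells$umis_b)
  expect_true(all(purity >= 0.99))
})

test_that("the DGE fast path reproduces the truth ledger", {
  run <- simulate_dge(small_params())
  expect_equal(unname(Matrix::colSums(run$dge)[run$truth$barcode]),
               run$truth$total_umis)
  mito <- run$profiles$annotation$gene_id[run$profiles$annotation$is_mito]
  expect_equal(
    unname(Matrix::colSums(run$dge[rownames(run$dge) %in% mito, ])[run$truth$barcode]),
    run$truth$mito_umis
  )
})

test_that("simulated mitochondrial load matches the generative fraction", {
  fr <- vapply(1:10, function(s) {
    tr <- simulate_dge(small_params(n_ambient_barcodes = 0, seed = 200 + s))$truth
    sum(tr$mito_umis) / sum(tr$total_umis)
  }, numeric(1))
  expect_lt(abs(mean(fr) - 0.1), 0.01)
})

test_that("parameters round-trip through the sidecar config", {
  p <- small_params(doublet_rate = 0.125)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_sim_params(p, path)
  expect_equal(read_sim_params(path), p)
})
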