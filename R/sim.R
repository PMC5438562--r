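#' Simulation parameters for a droplet run
#'
#' Bundles the generative quantities of the droplet-run simulator: how many
#' cell-containing beads there are, how the two (or more) species are mixed,
#' per-cell library sizes, the doublet rate, the ambient-only bead population,
#' PCR duplication, mitochondrial content and the bead-synthesis T-bias at the
#' last barcode base.
#'
#' Droplet loading is Poisson-limited, so the large majority of beads (over
#' 95 percent with the defaults) never meet a cell and capture only ambient
#' RNA; these beads produce the long low-read tail of the barcode-rank curve.
#'
#' @param n_cells Number of cell-containing barcodes (beads that captured at
#'   least one cell).
#' @param species_proportions Named numeric vector of mixing proportions, one
#'   entry per species; must sum to 1.
#' @param n_genes_per_species Genes simulated for each species.
#' @param expression_profile_dispersion Log-scale spread (sdlog) of per-gene
#'   mean expression; 0 gives a flat profile.
#' @param library_size_log_mean,library_size_log_sd Log-normal parameters of
#'   the per-cell total-molecule (UMI) count.
#' @param doublet_rate Fraction of cell-containing barcodes that hold two
#'   cells (co-encapsulation).
#' @param n_ambient_barcodes Number of ambient-only barcodes.
#' @param ambient_reads_mean Mean number of reads emitted per ambient-only
#'   barcode.
#' @param reads_per_umi_mean Mean reads per molecule (PCR duplication); must
#'   be at least 1. Each molecule is seen at least once.
#' @param mito_gene_fraction Fraction of each species' genes flagged
#'   mitochondrial.
#' @param mito_expression_fraction Expected fraction of a cell's UMIs drawn
#'   from mitochondrial genes.
#' @param last_base_t_error_prob Probability that a barcode's final (12th)
#'   base is overwritten with T, emulating bead-synthesis errors. Applied per
#'   bead: all reads of an affected barcode share the defect.
#' @param seed Integer master seed; every component draws from its own
#'   sub-stream derived from it, so e.g. changing `n_ambient_barcodes` does
#'   not perturb the cell draws.
#'
#' @return A validated `sim_params` list.
#' @seealso [simulate_run()], [simulate_dge()], [make_barnyard()]
#' @export
#' @examples
#' p <- sim_params(n_cells = 20, n_ambient_barcodes = 100, seed = 7)
#' run <- simulate_run(p)
#' head(run$reads)
sim_params <- function(n_cells = 100L,
                       species_proportions = c(human = 0.5, mouse = 0.5),
                       n_genes_per_species = 1000L,
                       expression_profile_dispersion = 1,
                       library_size_log_mean = log(8000),
                       library_size_log_sd = 0.45,
                       doublet_rate = 0.05,
                       n_ambient_barcodes = 2000L,
                       ambient_reads_mean = 30,
                       reads_per_umi_mean = 3,
                       mito_gene_fraction = 0.02,
                       mito_expression_fraction = 0.1,
                       last_base_t_error_prob = 0.05,
                       seed = 1L) {
  p <- list(
    n_cells = as.integer(n_cells),
    species_proportions = species_proportions,
    n_genes_per_species = as.integer(n_genes_per_species),
    expression_profile_dispersion = expression_profile_dispersion,
    library_size_log_mean = library_size_log_mean,
    library_size_log_sd = library_size_log_sd,
    doublet_rate = doublet_rate,
    n_ambient_barcodes = as.integer(n_ambient_barcodes),
    ambient_reads_mean = ambient_reads_mean,
    reads_per_umi_mean = reads_per_umi_mean,
    mito_gene_fraction = mito_gene_fraction,
    mito_expression_fraction = mito_expression_fraction,
    last_base_t_error_prob = last_base_t_error_prob,
    seed = as.integer(seed)
  )
  validate_sim_params(p)
  structure(p, class = "sim_params")
}

validate_sim_params <- function(p) {
  sp <- p$species_proportions
  if (is.null(names(sp)) || any(!nzchar(names(sp)))) {
    abort("`species_proportions` must be a named vector.")
  }
  if (any(sp < 0) || abs(sum(sp) - 1) > 1e-8) {
    abort("`species_proportions` must be non-negative and sum to 1.")
  }
  fracs <- c(
    doublet_rate = p$doublet_rate,
    mito_gene_fraction = p$mito_gene_fraction,
    mito_expression_fraction = p$mito_expression_fraction,
    last_base_t_error_prob = p$last_base_t_error_prob
  )
  bad <- fracs < 0 | fracs > 1
  if (any(bad)) {
    abort(sprintf("Fractions must lie in [0, 1]: %s.",
                  paste(names(fracs)[bad], collapse = ", ")))
  }
  if (p$n_cells < 0 || p$n_ambient_barcodes < 0) {
    abort("`n_cells` and `n_ambient_barcodes` must be non-negative.")
  }
  if (p$n_genes_per_species <= 0) abort("`n_genes_per_species` must be positive.")
  if (!is.finite(p$expression_profile_dispersion) || p$expression_profile_dispersion < 0) {
    abort("`expression_profile_dispersion` must be finite and non-negative.")
  }
  if (p$reads_per_umi_mean < 1) abort("`reads_per_umi_mean` must be >= 1.")
  if (p$ambient_reads_mean <= 0) abort("`ambient_reads_mean` must be positive.")
  invisible(p)
}

# Independent sub-streams per simulator component, derived from the master seed.
component_seeds <- function(seed) {
  set.seed(seed)
  setNames(
    sample.int(.Machine$integer.max - 1L, 6L),
    c("profiles", "barcodes", "cells", "ambient", "duplication", "corruption")
  )
}

#' Simulate per-species gene expression profiles
#'
#' Draws one mean-expression profile per species: log-normal gene weights with
#' sdlog `expression_profile_dispersion`, normalized to sum to 1, with the
#' mitochondrial genes jointly rescaled to carry probability mass
#' `mito_expression_fraction`. Also builds the matching gene annotation table
#' (species tag, mitochondrial flag, mean isoform length). Gene identifiers
#' are prefixed with the species label so two-species runs have disjoint gene
#' namespaces, matching the combined-reference convention.
#'
#' @param params A [sim_params()] object.
#' @return A list of class `expression_profiles` with elements `profiles`
#'   (named list of per-species probability vectors over that species' genes)
#'   and `annotation` (a tibble: `gene_id`, `species`, `is_mito`,
#'   `mean_isoform_length`).
#' @export
simulate_expression_profiles <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  validate_sim_params(params)
  seeds <- component_seeds(params$seed)
  set.seed(seeds[["profiles"]])

  ng <- params$n_genes_per_species
  n_mito <- as.integer(round(params$mito_gene_fraction * ng))
  if (n_mito == 0 && params$mito_expression_fraction > 0) {
    abort("`mito_expression_fraction` > 0 but no gene is flagged mitochondrial at this `mito_gene_fraction`.")
  }

  species <- names(params$species_proportions)
  profiles <- list()
  ann <- list()
  for (sp in species) {
    ids <- c(
      if (n_mito > 0) sprintf("%s_mt%02d", sp, seq_len(n_mito)),
      sprintf("%s_g%04d", sp, seq_len(ng - n_mito))
    )
    is_mito <- c(rep(TRUE, n_mito), rep(FALSE, ng - n_mito))
    w <- rlnorm(ng, meanlog = 0, sdlog = params$expression_profile_dispersion)
    mf <- if (n_mito > 0) params$mito_expression_fraction else 0
    prob <- numeric(ng)
    if (n_mito > 0) prob[is_mito] <- w[is_mito] / sum(w[is_mito]) * mf
    prob[!is_mito] <- w[!is_mito] / sum(w[!is_mito]) * (1 - mf)
    profiles[[sp]] <- setNames(prob, ids)
    ann[[sp]] <- tibble(
      gene_id = ids,
      species = sp,
      is_mito = is_mito,
      mean_isoform_length = round(rlnorm(ng, log(1500), 0.5))
    )
  }
  structure(
    list(profiles = profiles, annotation = dplyr::bind_rows(ann)),
    class = "expression_profiles"
  )
}

# Draw molecule (gene) counts for each cell instance and aggregate to barcodes.
# Returns gene x barcode-slot integer matrix plus per-slot metadata.
draw_cell_molecules <- function(params, prof_global, instances) {
  G <- length(prof_global[[1L]])
  if (nrow(instances) == 0) {
    return(matrix(0L, G, 0L))
  }
  counts <- vapply(seq_len(nrow(instances)), function(i) {
    rmultinom(1L, instances$lib_size[i], prof_global[[instances$species[i]]])[, 1L]
  }, integer(G))
  n_slots <- max(instances$slot)
  agg <- matrix(0L, G, n_slots)
  for (i in seq_len(nrow(instances))) {
    s <- instances$slot[i]
    agg[, s] <- agg[, s] + counts[, i]
  }
  agg
}

# Assign distinct UMI indices within each (barcode, gene): draw uniformly over
# the 4^8 UMI space and redraw collisions.
draw_umis <- function(bc_idx, gene_idx, n_genes_total) {
  m <- length(bc_idx)
  umi <- sample.int(N_UMI_SPACE, m, replace = TRUE)
  key <- (bc_idx - 1) * (n_genes_total * N_UMI_SPACE) + (gene_idx - 1) * N_UMI_SPACE + umi
  repeat {
    d <- duplicated(key)
    if (!any(d)) break
    umi[d] <- sample.int(N_UMI_SPACE, sum(d), replace = TRUE)
    key[d] <- (bc_idx[d] - 1) * (n_genes_total * N_UMI_SPACE) + (gene_idx[d] - 1) * N_UMI_SPACE + umi[d]
  }
  umi
}

# Shared generative core: everything up to the molecule layer.
# Returns barcode-level metadata and molecule-level (bc_idx, gene_idx) vectors.
simulate_molecules <- function(params) {
  validate_sim_params(params)
  seeds <- component_seeds(params$seed)
  prof <- simulate_expression_profiles(params)
  species <- names(params$species_proportions)
  gene_ids <- prof$annotation$gene_id
  G <- length(gene_ids)
  is_mito <- prof$annotation$is_mito

  # per-species probability vectors on the global gene axis
  prof_global <- lapply(species, function(sp) {
    v <- numeric(G)
    v[prof$annotation$species == sp] <- prof$profiles[[sp]]
    v
  })
  names(prof_global) <- species

  n_bc <- params$n_cells + params$n_ambient_barcodes

  # --- cell-containing barcodes ---------------------------------------------
  set.seed(seeds[["cells"]])
  nc <- params$n_cells
  origin <- character(0)
  sp1 <- sp2 <- character(0)
  instances <- tibble(slot = integer(0), species = character(0), lib_size = integer(0))
  if (nc > 0) {
    is_doublet <- runif(nc) < params$doublet_rate
    origin <- ifelse(is_doublet, "doublet", "singlet")
    sp1 <- sample(species, nc, replace = TRUE, prob = params$species_proportions)
    sp2 <- rep(NA_character_, nc)
    sp2[is_doublet] <- sample(species, sum(is_doublet), replace = TRUE,
                              prob = params$species_proportions)
    slot <- c(seq_len(nc), which(is_doublet))
    inst_sp <- c(sp1, sp2[is_doublet])
    lib <- pmax(1L, as.integer(round(rlnorm(length(slot),
                                            params$library_size_log_mean,
                                            params$library_size_log_sd))))
    instances <- tibble(slot = slot, species = inst_sp, lib_size = lib)
  }
  cell_counts <- draw_cell_molecules(params, prof_global, instances)

  cell_mol_gene <- integer(0)
  cell_mol_bc <- integer(0)
  if (nc > 0 && sum(cell_counts) > 0) {
    cnt <- as.vector(cell_counts)
    cell_mol_gene <- rep(rep.int(seq_len(G), ncol(cell_counts)), cnt)
    cell_mol_bc <- rep(rep(seq_len(ncol(cell_counts)), each = G), cnt)
  }

  # --- ambient-only barcodes ------------------------------------------------
  set.seed(seeds[["ambient"]])
  na <- params$n_ambient_barcodes
  amb_mol_gene <- integer(0)
  amb_mol_bc <- integer(0)
  if (na > 0) {
    pooled <- Reduce(`+`, Map(`*`, prof_global, params$species_proportions))
    mol_mean <- max(params$ambient_reads_mean / params$reads_per_umi_mean - 1, 0)
    n_mol <- 1L + rpois(na, mol_mean)
    amb_mol_gene <- sample.int(G, sum(n_mol), replace = TRUE, prob = pooled)
    amb_mol_bc <- rep(nc + seq_len(na), n_mol)
  }

  mol_bc <- c(cell_mol_bc, amb_mol_bc)
  mol_gene <- c(cell_mol_gene, amb_mol_gene)

  # --- barcodes and bead-synthesis corruption -------------------------------
  set.seed(seeds[["barcodes"]])
  bc <- random_barcodes(n_bc)
  set.seed(seeds[["corruption"]])
  corrupted <- runif(n_bc) < params$last_base_t_error_prob
  substr(bc[corrupted], BARCODE_LENGTH, BARCODE_LENGTH) <- "T"
  while (anyDuplicated(bc)) {
    d <- which(duplicated(bc))
    bc[d] <- random_dna(length(d), BARCODE_LENGTH)
    substr(bc[d][corrupted[d]], BARCODE_LENGTH, BARCODE_LENGTH) <- "T"
  }

  umi_count <- tabulate(mol_bc, n_bc)
  mito_count <- tabulate(mol_bc[is_mito[mol_gene]], n_bc)
  truth <- tibble(
    barcode = bc,
    origin = c(origin, rep("ambient_only", na)),
    species_1 = c(sp1, rep(NA_character_, na)),
    species_2 = c(if (nc > 0) sp2 else character(0), rep(NA_character_, na)),
    total_umis = umi_count,
    mito_umis = mito_count,
    last_base_corrupted = corrupted
  )

  list(
    truth = truth, profiles = prof, gene_ids = gene_ids, barcodes = bc,
    mol_bc = mol_bc, mol_gene = mol_gene, seeds = seeds
  )
}

#' Simulate a droplet run at read level
#'
#' Generates a full tagged-read table with ground truth. Every cell-containing
#' barcode draws a log-normal library size and samples distinct
#' (UMI, gene) molecules from its species' expression profile (doublet
#' barcodes mix the molecules of two independently drawn cells); ambient-only
#' barcodes draw a few molecules from the pooled pseudobulk of all species.
#' Each molecule is then emitted as `1 + Poisson(reads_per_umi_mean - 1)`
#' duplicate reads, so every molecule is sequenced at least once. Finally the
#' 12th base of each barcode is overwritten with T with probability
#' `last_base_t_error_prob` (whole-bead corruption, recorded in the truth
#' table; collisions with existing barcodes are regenerated).
#'
#' @param params A [sim_params()] object.
#' @return A list of class `droplet_run`: `reads` (tibble `barcode`, `umi`,
#'   `gene`), `truth` (tibble with per-barcode `origin`, species labels, true
#'   UMI and mitochondrial-UMI counts, corruption flag), `profiles`
#'   (see [simulate_expression_profiles()]) and `params`.
#' @export
simulate_run <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  sim <- simulate_molecules(params)
  m <- length(sim$mol_bc)
  G <- length(sim$gene_ids)

  set.seed(sim$seeds[["duplication"]])
  umi_idx <- draw_umis(sim$mol_bc, sim$mol_gene, G)
  n_dup <- 1L + rpois(m, params$reads_per_umi_mean - 1)
  rix <- rep(seq_len(m), n_dup)

  reads <- tibble(
    barcode = sim$barcodes[sim$mol_bc[rix]],
    umi = umi_lookup()[umi_idx[rix]],
    gene = sim$gene_ids[sim$mol_gene[rix]]
  )
  truth <- sim$truth
  truth$total_reads <- tabulate(sim$mol_bc[rix], nrow(truth))

  structure(
    list(reads = reads, truth = truth, profiles = sim$profiles, params = params),
    class = "droplet_run"
  )
}

#' Simulate a droplet run directly at the DGE level
#'
#' Fast path that produces the digital gene expression matrix a perfect UMI
#' counter would recover from [simulate_run()] with the same parameters: the
#' generative model is identical through the molecule layer, but UMI strings
#' and PCR read duplication are skipped (UMI collisions are redrawn in the
#' read-level path, so molecule counts and distinct-UMI counts coincide).
#' Intended for parameter-recovery experiments at larger cell numbers.
#'
#' @inheritParams simulate_run
#' @return A list of class `droplet_run` with elements `dge` (sparse genes x
#'   barcodes UMI count matrix including ambient-only barcodes), `truth`,
#'   `profiles` and `params`.
#' @export
simulate_dge <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  sim <- simulate_molecules(params)
  G <- length(sim$gene_ids)
  dge <- sparseMatrix(
    i = sim$mol_gene, j = sim$mol_bc, x = 1,
    dims = c(G, nrow(sim$truth)),
    dimnames = list(sim$gene_ids, sim$barcodes)
  )
  structure(
    list(dge = dge, truth = sim$truth, profiles = sim$profiles, params = params),
    class = "droplet_run"
  )
}

#' Simulate a two-species (barnyard) droplet run
#'
#' Convenience wrapper around [simulate_run()] / [simulate_dge()] for the
#' mixed-species design used to diagnose doublets: exactly two species with
#' disjoint, species-prefixed gene namespaces.
#'
#' @inheritParams simulate_run
#' @param level `"reads"` for a tagged-read stream, `"dge"` for the fast
#'   molecule-count path.
#' @return A `droplet_run` (see [simulate_run()]).
#' @export
make_barnyard <- function(params, level = c("reads", "dge")) {
  stopifnot(inherits(params, "sim_params"))
  level <- match.arg(level)
  if (length(params$species_proportions) != 2L) {
    abort("A barnyard run requires exactly two species.")
  }
  if (level == "reads") simulate_run(params) else simulate_dge(params)
}

#' @export
print.droplet_run <- function(x, ...) {
  tr <- x$truth
  cat(sprintf(
    "<droplet_run> %d barcodes (%d cell-containing, %d ambient-only)\n",
    nrow(tr), sum(tr$origin != "ambient_only"), sum(tr$origin == "ambient_only")
  ))
  if (!is.null(x$reads)) cat(sprintf("  reads: %d tagged reads\n", nrow(x$reads)))
  if (!is.null(x$dge)) cat(sprintf("  dge: %d genes x %d barcodes\n", nrow(x$dge), ncol(x$dge)))
  invisible(x)
}
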