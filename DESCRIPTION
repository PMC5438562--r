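Package: dropkit
Title: Quality Control and Exploratory Analysis for Droplet Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for exploratory analysis and quality control of droplet-based
    single-cell RNA-seq experiments: digital UMI counting from tagged reads,
    barcode-rank knee detection for cell calling, per-cell QC (genes, UMIs,
    non-mitochondrial content), the 90 percent species-purity rule and doublet-rate
    extrapolation for mixed-species (barnyard) runs, ATPM/RPKM normalization and
    log-space cross-sample correlation. Includes a droplet-run simulator with
    ground truth (ambient-only beads, doublets, PCR duplication, barcode-synthesis
    T-bias) so every stage can be validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
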