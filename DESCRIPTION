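Package: cellgex
Title: Cell-Based Simulation of Time-Course Bulk and Single-Cell Gene
    Expression Data
Version: 0.9.0
Authors@R:
    person("cellgex", "developers", email = "cellgex@example.org",
           role = c("aut", "cre"))
Description: Couples an off-lattice, cell-center Monte Carlo model of a
    growing, dividing and mechanically interacting cell population to a
    pathway-activity model of transcription, producing time-course bulk
    microarray, bulk RNA-seq and single-cell RNA-seq matrices with a fully
    known ground truth.  Pathway activity in each simulated cell (cell-cycle
    phase transitions, contact inhibition, growth rate, cell-type identity)
    is mapped to per-gene expression through calibrated expression ranges,
    and platform-specific measurement-error models (Gaussian log-intensity
    noise, negative-binomial counts, negative-binomial counts with logistic
    dropout) generate the observed data.  Intended for benchmarking
    time-course omics analysis methods against a known cellular and
    molecular ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
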