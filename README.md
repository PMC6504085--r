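# cellgex

Simulation of time-course bulk and single-cell gene expression data from a
mechanistic model of a growing cell population, with a fully known ground
truth.

Benchmarking time-course omics methods (clustering, trajectory inference,
matrix factorization, differential expression over time) is hard because
real datasets come without a ground truth for the cellular processes that
generated them. cellgex produces such datasets synthetically, but from
*biological* rather than purely statistical parameters: an off-lattice,
cell-center Monte Carlo model grows, divides and mechanically crowds a
2-D cell population; pathway activity (cell-cycle phase transitions,
contact inhibition, growth rate, cell-type identity) is read off each
simulated cell; and calibrated per-gene expression ranges plus
platform-specific error models turn those activities into microarray,
bulk RNA-seq, or single-cell RNA-seq matrices. Every output ships with
the underlying trajectory and the pathway-activity matrix that generated
it.

## The model in brief

**Cell layer.** Cells are disks (mitotic cells: two-disk dumbbells) whose
migration, growth and division are Metropolis Monte Carlo trials accepted
with probability min(1, e^(−ΔE)), where ΔE is the change in a pairwise
energy with a quadratic overlap penalty and a short-range adhesion well.
Cycle lengths are truncated-normal per cell type; interphase growth
follows an area-linear schedule, so crowded cells slow down and a bounded
domain saturates — contact inhibition emerges from the energetics.

**Expression layer.** For pathway k with activity P_k ∈ [0, 1] and a gene
i annotated to it with calibrated range (Gmin, Gmax):

    g_i = mean over pathways k of [ P_k * Gmax_ik + (1 − P_k) * Gmin_ik ]

In bulk mode P_k is first averaged over the N sampled cells (one column
per time point); in single-cell mode each sampled cell keeps its own P_k
(one column per cell). Measurement error is platform specific: Gaussian
noise (microarray), negative-binomial counts (bulk RNA-seq), or
negative-binomial counts with logistic dropout and log-normal per-cell
library sizes (single-cell RNA-seq).

See `vignettes/cellgex-methods.Rmd` for assumptions, parameter defaults
and their rationale, and known limitations.

## Worked example

```r
library(cellgex)

traj <- run_cell_model(model_params(100, 72, 0.01, seed = 1),
                       cell_type("tumor", cycle_mean = 24, cycle_sd = 4))
traj
#> <cell_trajectory> 72 h, 73 snapshots, 100 -> 812 cells, 2607 events

iv <- division_intervals(traj, max_birth = 36)
sprintf("%d full division intervals, mean %.1f h, sd %.1f h",
        length(iv), mean(iv), sd(iv))
#> "380 full division intervals, mean 24.4 h, sd 4.1 h"
```

100 founder cells at initial area fraction 0.01 grow for 72 hours; the
population triples-and-some to 812 cells, and the realized division
intervals recover the configured 24 ± 4 h cycle distribution (the
`max_birth` cohort filter avoids the inspection bias of a growing
population — see the vignette).

```r
pw <- calibrate_from_distribution(
  pathway_phase_transition("mitosis", sprintf("mito_g%02d", 1:10), "M"),
  lambda = 20, stddev = 2, seed = 1)

res <- simulate_gene_expression(traj, list(pw),
  gene_expression_params(sample_freq = 24, n_cells = 50, seed = 1))
res
#> <expression_result> microarray, 10 genes x 4 samples

round(res$noisy_matrix[1:3, ], 2)
#>             t0   t24   t48   t72
#> mito_g01 90.24 90.48 90.26 90.65
#> mito_g02  1.15  1.58  1.20  1.55
#> mito_g03  8.59  9.68  8.96  8.66

round(res$activity_matrix, 3)
#>         t0  t24 t48 t72
#> mitosis  0 0.04   0   0
```

Ten genes follow an M-entry pathway whose ranges were calibrated from an
exponential(mean 20) / half-normal(sd 2) distribution. Each column is the
bulk mean over 50 sampled cells plus Gaussian noise; because only a small
fraction of an unsynchronized population enters mitosis within the 1-hour
event window at any instant, the ground-truth bulk activity (bottom
matrix) hovers near 1/24 ≈ 0.04 and each gene stays near its Gmin, which
is exactly the behavior a method under benchmark has to detect.

## Packaged scenarios

```r
sc <- run_scenario("bulk_microarray", seed = 1)      # 150 genes x 43 times
sc <- run_scenario("singlecell_twotype", seed = 1)   # NB + dropout counts
sc <- run_scenario("growth_confounded", seed = 1)    # disjoint + confounded
```

`bulk_microarray`: a 168-h bounded-domain run (growth slows as the domain
fills) with S-transition, M-transition and contact-inhibition pathways,
150 genes, microarray samples every 4 h → 43 time points.
`singlecell_twotype`: cell types A (12 ± 4 h) and B (36 ± 4 h) with
binary identity pathways on disjoint gene sets.
`growth_confounded`: two identical cell types plus a growth-rate pathway,
emitted twice from the same trajectory — once with disjoint gene sets and
once with the growth pathway covering both identity sets — for testing a
method's sensitivity to annotation confounding.

## Command line

```sh
LAUNCHER=$(Rscript -e 'cat(system.file("cli/cellgex.R", package = "cellgex"))')
Rscript "$LAUNCHER" simulate  --config config.json --seed 7 --out out/
Rscript "$LAUNCHER" scenario bulk_microarray --seed 1 --out out/
```

Subcommands: `cell-model`, `expression`, `simulate`, `scenario`.
Configs are JSON (schema-validated, unknown keys rejected); outputs are
TSV matrices or a Matrix Market triplet (`counts.mtx` + `features.tsv` +
`barcodes.tsv`), the trajectory as JSON Lines, and the effective config.
Identical (config, seed) pairs reproduce outputs byte for byte.

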