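# Packaged benchmark scenarios.  Sizes and noise levels below are package
# defaults chosen for desk-scale runs (single CPU, minutes); each can be
# overridden through the `overrides` map.

scenario_defaults <- list(
  bulk_microarray = list(
    initial_num = 100, hours = 168, density = 0.05, boundary = "circular",
    cycle_mean = 24, cycle_sd = 4,
    genes_per_pathway = 50, lambda = 20, stddev = 2,
    sample_freq = 4, n_cells = 50, microarray_sd = 0.25,
    transition_window = 1),
  singlecell_twotype = list(
    initial_num = 100, hours = 48, density = 0.01, boundary = "unbounded",
    cycle_mean_a = 12, cycle_sd_a = 4, cycle_mean_b = 36, cycle_sd_b = 4,
    genes_per_type = 50, genes_per_transition = 25,
    lambda = 20, stddev = 2,
    sample_freq = 8, n_cells = 30, nb_dispersion = 0.1,
    dropout_shape = 1, transition_window = 1),
  growth_confounded = list(
    initial_num = 100, hours = 96, density = 0.05, boundary = "circular",
    cycle_mean = 24, cycle_sd = 4,
    genes_per_type = 50, genes_growth = 50,
    lambda = 20, stddev = 2,
    sample_freq = 12, n_cells = 40, nb_dispersion = 0.1,
    dropout_shape = 1)
)

merge_overrides <- function(name, overrides) {
  d <- scenario_defaults[[name]]
  bad <- setdiff(names(overrides), names(d))
  if (length(bad) > 0) {
    stop("unknown override(s) for scenario '", name, "': ",
         paste(bad, collapse = ", "))
  }
  utils::modifyList(d, overrides)
}

#' Bulk microarray time-course scenario
#'
#' A 168-hour bounded-domain run of a single cell type whose growth slows
#' as the domain fills, with three pathways of 50 genes each: entry into S
#' phase, entry into M phase, and contact inhibition.  Microarray samples
#' are drawn every 4 hours, giving 43 time points at the default duration.
#'
#' @param overrides Named list of parameter overrides (see
#'   `cellgex:::scenario_defaults$bulk_microarray`).
#' @param seed RNG seed; the scenario is fully reproducible from it.
#' @return List with `result` (an `expression_result`), `trajectory`,
#'   `pathways` and `params`.
#' @export
scenario_bulk_microarray <- function(overrides = list(), seed = 1) {
  o <- merge_overrides("bulk_microarray", overrides)
  params <- model_params(o$initial_num, o$hours, o$density,
                         boundary = o$boundary, seed = seed)
  type <- cell_type("tumor", cycle_mean = o$cycle_mean,
                    cycle_sd = o$cycle_sd, proportion = 1)
  trajectory <- run_cell_model(params, type)

  cal_seed <- derive_seed(seed, "calibration")
  g <- o$genes_per_pathway
  pathways <- list(
    calibrate_from_distribution(
      pathway_phase_transition("sphase", placeholder_genes("sphase", g),
                               "S", o$transition_window),
      o$lambda, o$stddev, seed = cal_seed),
    calibrate_from_distribution(
      pathway_phase_transition("mitosis", placeholder_genes("mitosis", g),
                               "M", o$transition_window),
      o$lambda, o$stddev, seed = cal_seed + 1),
    calibrate_from_distribution(
      pathway_contact_inhibition("contact_inhibition",
                                 placeholder_genes("ci", g)),
      o$lambda, o$stddev, seed = cal_seed + 2))

  ep <- gene_expression_params(sample_freq = o$sample_freq,
                               n_cells = o$n_cells,
                               microarray_sd = o$microarray_sd,
                               seed = seed)
  result <- simulate_gene_expression(trajectory, pathways, ep)
  list(result = result, trajectory = trajectory, pathways = pathways,
       params = params)
}

#' Two-cell-type single-cell RNA-seq scenario
#'
#' An equally mixed population of a fast-cycling type A (12 +/- 4 h) and a
#' slow-cycling type B (36 +/- 4 h).  Each type is labeled by a binary
#' identity pathway over its own disjoint gene set; S- and M-entry
#' pathways are shared.  Output is single-cell RNA-seq counts with
#' negative-binomial noise and logistic dropout.
#'
#' @inheritParams scenario_bulk_microarray
#' @return As [scenario_bulk_microarray()].
#' @export
scenario_singlecell_twotype <- function(overrides = list(), seed = 1) {
  o <- merge_overrides("singlecell_twotype", overrides)
  params <- model_params(o$initial_num, o$hours, o$density,
                         boundary = o$boundary, seed = seed)
  types <- list(
    cell_type("A", cycle_mean = o$cycle_mean_a, cycle_sd = o$cycle_sd_a,
              proportion = 0.5),
    cell_type("B", cycle_mean = o$cycle_mean_b, cycle_sd = o$cycle_sd_b,
              proportion = 0.5))
  trajectory <- run_cell_model(params, types)

  cal_seed <- derive_seed(seed, "calibration")
  pathways <- list(
    calibrate_from_distribution(
      pathway_cell_type("typeA",
                        placeholder_genes("typeA", o$genes_per_type), "A"),
      o$lambda, o$stddev, seed = cal_seed),
    calibrate_from_distribution(
      pathway_cell_type("typeB",
                        placeholder_genes("typeB", o$genes_per_type), "B"),
      o$lambda, o$stddev, seed = cal_seed + 1),
    calibrate_from_distribution(
      pathway_phase_transition(
        "sphase", placeholder_genes("sphase", o$genes_per_transition),
        "S", o$transition_window),
      o$lambda, o$stddev, seed = cal_seed + 2),
    calibrate_from_distribution(
      pathway_phase_transition(
        "mitosis", placeholder_genes("mitosis", o$genes_per_transition),
        "M", o$transition_window),
      o$lambda, o$stddev, seed = cal_seed + 3))

  ep <- gene_expression_params(sample_freq = o$sample_freq,
                               n_cells = o$n_cells, rnaseq = TRUE,
                               single_cell = TRUE,
                               nb_dispersion = o$nb_dispersion,
                               dropout_shape = o$dropout_shape,
                               seed = seed)
  result <- simulate_gene_expression(trajectory, pathways, ep)
  list(result = result, trajectory = trajectory, pathways = pathways,
       params = params)
}

#' Growth-pathway confounding scenario
#'
#' Two cell types with identical growth properties, each with an identity
#' pathway, plus a third pathway proportional to each cell's realized
#' growth rate.  Two single-cell datasets are generated from the same
#' trajectory and sampling: one where all three pathways have disjoint
#' gene sets, and one where the growth pathway's gene set is the union of
#' both type gene sets, confounding type identity with growth.  Only the
#' annotation overlap differs between the two datasets.
#'
#' @inheritParams scenario_bulk_microarray
#' @param confounded When `NULL` (default) both datasets are returned;
#'   `TRUE`/`FALSE` selects one.
#' @return List with `disjoint` and/or `confounded` expression results,
#'   plus the shared `trajectory`, `pathways` and `params`.
#' @export
scenario_growth_confounded <- function(overrides = list(), seed = 1,
                                       confounded = NULL) {
  o <- merge_overrides("growth_confounded", overrides)
  params <- model_params(o$initial_num, o$hours, o$density,
                         boundary = o$boundary, seed = seed)
  types <- list(
    cell_type("A", cycle_mean = o$cycle_mean, cycle_sd = o$cycle_sd,
              proportion = 0.5),
    cell_type("B", cycle_mean = o$cycle_mean, cycle_sd = o$cycle_sd,
              proportion = 0.5))
  trajectory <- run_cell_model(params, types)

  genes_a <- placeholder_genes("typeA", o$genes_per_type)
  genes_b <- placeholder_genes("typeB", o$genes_per_type)
  cal_seed <- derive_seed(seed, "calibration")
  base_pathways <- function(growth_genes, growth_cal_seed) {
    list(
      calibrate_from_distribution(pathway_cell_type("typeA", genes_a, "A"),
                                  o$lambda, o$stddev, seed = cal_seed),
      calibrate_from_distribution(pathway_cell_type("typeB", genes_b, "B"),
                                  o$lambda, o$stddev, seed = cal_seed + 1),
      calibrate_from_distribution(
        pathway_growth_rate("growth", growth_genes),
        o$lambda, o$stddev, seed = growth_cal_seed))
  }
  pw_disjoint <- base_pathways(placeholder_genes("growth", o$genes_growth),
                               cal_seed + 2)
  pw_confounded <- base_pathways(c(genes_a, genes_b), cal_seed + 3)

  ep <- gene_expression_params(sample_freq = o$sample_freq,
                               n_cells = o$n_cells, rnaseq = TRUE,
                               single_cell = TRUE,
                               nb_dispersion = o$nb_dispersion,
                               dropout_shape = o$dropout_shape,
                               seed = seed)
  out <- list(trajectory = trajectory, params = params)
  if (is.null(confounded) || !isTRUE(confounded)) {
    out$disjoint <- simulate_gene_expression(trajectory, pw_disjoint, ep)
    out$pathways_disjoint <- pw_disjoint
  }
  if (is.null(confounded) || isTRUE(confounded)) {
    out$confounded <- simulate_gene_expression(trajectory, pw_confounded,
                                               ep)
    out$pathways_confounded <- pw_confounded
  }
  out
}

#' Run a named scenario
#'
#' @param name One of `"bulk_microarray"`, `"singlecell_twotype"`,
#'   `"growth_confounded"`.
#' @param overrides Named list of scenario parameter overrides.
#' @param seed RNG seed.
#' @param confounded For `growth_confounded` only.
#' @return The scenario's result list.
#' @export
run_scenario <- function(name = c("bulk_microarray", "singlecell_twotype",
                                  "growth_confounded"),
                         overrides = list(), seed = 1, confounded = NULL) {
  name <- match.arg(name)
  switch(name,
         bulk_microarray = scenario_bulk_microarray(overrides, seed),
         singlecell_twotype = scenario_singlecell_twotype(overrides, seed),
         growth_confounded = scenario_growth_confounded(overrides, seed,
                                                        confounded))
}
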