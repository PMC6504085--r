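# lazily built, cached simulation fixtures shared across test files

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env, inherits = FALSE)) {
    assign(name, expr, envir = .fixture_env)
  }
  get(name, envir = .fixture_env, inherits = FALSE)
}

# sparse unbounded run of a fast-cycling type (division statistics, growth
# law, pathway rules)
fx_sparse_traj <- function() fixture("sparse_traj",
  run_cell_model(model_params(40, 72, 0.002, seed = 42),
                 cell_type("A", cycle_mean = 12, cycle_sd = 4)))

# small mixed-type run (pathway / expression plumbing)
fx_small_traj <- function() fixture("small_traj",
  run_cell_model(model_params(30, 12, 0.02, seed = 7),
                 list(cell_type("A", cycle_mean = 12, cycle_sd = 3,
                                proportion = 0.5),
                      cell_type("B", cycle_mean = 20, cycle_sd = 3,
                                proportion = 0.5))))

# full bounded bulk scenario (43 time points, crowding properties)
fx_bulk <- function() fixture("bulk", scenario_bulk_microarray(seed = 3))

# single-cell two-type scenario
fx_sc <- function() fixture("sc", scenario_singlecell_twotype(seed = 2))

# calibrated toy pathways over the small trajectory's processes
fx_small_pathways <- function() fixture("small_pathways", {
  list(
    calibrate_from_distribution(
      pathway_cell_type("pwA", paste0("a", 1:6), "A"), 20, 2, seed = 5),
    calibrate_from_distribution(
      pathway_cell_type("pwB", paste0("b", 1:6), "B"), 20, 2, seed = 6),
    calibrate_from_distribution(
      pathway_phase_transition("pwM", paste0("m", 1:4), "M", 1),
      20, 2, seed = 7))
})

write_min_config <- function(path, seed = 7) {
  cfg <- list(
    seed = seed,
    model = list(initial_num = 25, hours = 8, density = 0.02),
    cell_types = list(list(name = "A", cycle_mean = 12, cycle_sd = 3,
                           proportion = 1)),
    pathways = list(
      list(name = "sphase", n_genes = 8,
           rule = list(name = "phase_transition", phase = "S"),
           calibration = list(method = "distribution", lambda = 20,
                              stddev = 2)),
      list(name = "ci", n_genes = 8, rule = "contact_inhibition")),
    expression = list(sample_freq = 4, n_cells = 10))
  jsonlite::write_json(cfg, path, auto_unbox = TRUE)
  path
}
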