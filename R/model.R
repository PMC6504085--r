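#' Local density of cells
#'
#' Fraction of the annulus between a cell's own radius and
#' `radius_factor` times that radius covered by other cells' disks,
#' estimated on a deterministic equal-area polar quadrature grid and
#' clamped to \[0, 1\].  This is the crowding measure used by the
#' contact-inhibition pathway.
#'
#' @param population A `cell_population` or trajectory snapshot matrix.
#' @param cell Row index of one cell, or `NULL` for all cells.
#' @param radius_factor Outer radius of the annulus as a multiple of the
#'   cell radius; must be > 1.
#' @param n_r,n_theta Radial and angular quadrature resolution.
#' @return Numeric value(s) in \[0, 1\].
#' @export
local_density <- function(population, cell = NULL, radius_factor = 3,
                          n_r = 16, n_theta = 64) {
  if (radius_factor <= 1) stop("radius_factor must be > 1")
  out <- cpp_local_density(as_pop_matrix(population),
                           types_table(attr(population, "types")),
                           radius_factor, n_r, n_theta)
  if (is.null(cell)) out else out[cell]
}

#' One Monte Carlo sweep
#'
#' Performs `N` trial moves (`N` = population size), each picking a uniform
#' random cell and a trial kind chosen uniformly among the kinds currently
#' legal for that cell: migration (displacement up to `max_migration`),
#' growth (one scheduled area increment, only when the cell's cycle
#' schedule is due) or, in mitosis, dumbbell deformation.  Each trial is
#' accepted with [accept_probability()] of the change in total pairwise
#' energy.  The sweep then advances time by `1 / mc_steps_per_hour` hours
#' and completes any divisions whose mitosis deadline has passed.
#'
#' @param population A `cell_population`.
#' @param params A [model_params()].
#' @param t Current simulation time in hours.
#' @param energy Running total energy; computed from scratch when `NULL`.
#' @return A list with elements `population`, `time`, `energy`
#'   (incrementally tracked) and `events` (data frame of divisions and
#'   phase entries during the sweep).
#' @export
monte_carlo_step <- function(population, params, t = 0, energy = NULL) {
  ep <- engine_params(params, attr(population, "domain_radius"))
  tt <- types_table(attr(population, "types"))
  mat <- as_pop_matrix(population)
  if (is.null(energy)) energy <- cpp_total_energy(mat, ep, tt)
  next_id <- as.integer(max(mat[, "id"]) + 1)
  res <- cpp_sweep(mat, ep, tt, t, energy, next_id)
  res$population <- new_population(res$population,
                                   attr(population, "types"),
                                   attr(population, "domain_radius"),
                                   attr(population, "density"))
  res
}

#' Run the off-lattice cell model
#'
#' Seeds a population (see [seed_population()]) and runs
#' `hours * mc_steps_per_hour` Monte Carlo sweeps, recording a snapshot
#' every `record_every` hours together with each cell's local density and
#' realized growth rate, and logging every division and S/M phase entry.
#' Fully reproducible from `params$seed`.
#'
#' @param params A [model_params()].
#' @param types A [cell_type()] or list of them.
#' @param seed Optional seed overriding `params$seed`.
#' @return A `cell_trajectory`: list with `times`, `snapshots` (one data
#'   frame per time), `events`, `energy` (tracked vs recomputed totals per
#'   snapshot), `params`, `types` and `seed`.
#' @examples
#' traj <- run_cell_model(model_params(20, 5, 0.01, seed = 1),
#'                        cell_type("A", cycle_mean = 12, cycle_sd = 4))
#' @export
run_cell_model <- function(params, types, seed = NULL) {
  stopifnot(inherits(params, "model_params"))
  seed <- seed %||% params$seed
  set_stream_seed(seed, "model")
  if (inherits(types, "cell_type")) types <- list(types)
  types <- check_cell_types(types)

  pop <- seed_population(params, types)
  ep <- engine_params(params, attr(pop, "domain_radius"))
  tt <- types_table(types)
  res <- cpp_run(as_pop_matrix(pop), ep, tt, params$hours,
                 params$record_every, params$radius_factor,
                 params$density_grid[1], params$density_grid[2])

  snapshots <- lapply(res$snapshots, function(s) {
    df <- population_df(s$state, types)
    df$local_density <- s$local_density
    df$growth_rate <- s$growth_rate
    df
  })
  events <- as.data.frame(res$events)
  tn <- vapply(types, `[[`, character(1), "name")
  events$type <- tn[events$type]

  structure(list(times = res$times, snapshots = snapshots, events = events,
                 energy = data.frame(time = res$times,
                                     tracked = res$energy_tracked,
                                     brute = res$energy_brute),
                 params = params, types = types, seed = seed,
                 domain_radius = attr(pop, "domain_radius")),
            class = "cell_trajectory")
}

#' @export
print.cell_trajectory <- function(x, ...) {
  n0 <- nrow(x$snapshots[[1]])
  n1 <- nrow(x$snapshots[[length(x$snapshots)]])
  cat(sprintf(paste0("<cell_trajectory> %.0f h, %d snapshots, ",
                     "%d -> %d cells, %d events\n"),
              max(x$times), length(x$times), n0, n1, nrow(x$events)))
  invisible(x)
}

# index of the snapshot nearest to time t (ties resolve to the earlier one)
nearest_snapshot <- function(trajectory, t) {
  which.min(abs(trajectory$times - t))
}

#' Extract the population snapshot nearest a time point
#'
#' @param trajectory A `cell_trajectory`.
#' @param t Time in hours.
#' @param exact Require a snapshot recorded exactly at `t`.
#' @return Data frame of cell states.
#' @export
snapshot_at <- function(trajectory, t, exact = FALSE) {
  i <- nearest_snapshot(trajectory, t)
  if (exact && abs(trajectory$times[i] - t) > 1e-9) {
    stop("no snapshot recorded at t = ", t)
  }
  trajectory$snapshots[[i]]
}

#' Realized division intervals
#'
#' Time from a cell's birth to its division, for every logged division
#' event.  Founder cells (seeded with random interphase progress, so their
#' nominal birth time is negative) are excluded by default because their
#' first interval is not a full cycle.
#'
#' In a growing population observed over a finite window, divisions of
#' fast-cycling cells are over-represented (a branching-process inspection
#' bias), which deflates the naive interval mean.  Restricting to a birth
#' cohort early enough that essentially every member divides inside the
#' window (`max_birth`) removes this bias, because cycle lengths are drawn
#' independently at birth.
#'
#' @param trajectory A `cell_trajectory`.
#' @param type Optional cell-type name filter.
#' @param exclude_founders Drop divisions of seeded cells.
#' @param max_birth Only divisions of cells born at or before this time
#'   are counted (`Inf` keeps all; see Details for why you may not want
#'   that).
#' @return Numeric vector of intervals in hours.
#' @export
division_intervals <- function(trajectory, type = NULL,
                               exclude_founders = TRUE, max_birth = Inf) {
  ev <- trajectory$events
  ev <- ev[ev$event == "division", , drop = FALSE]
  if (!is.null(type)) ev <- ev[ev$type == type, , drop = FALSE]
  if (exclude_founders) ev <- ev[ev$birth_time > 0, , drop = FALSE]
  ev <- ev[ev$birth_time <= max_birth, , drop = FALSE]
  ev$time - ev$birth_time
}

#' Deterministic cell-cycle progression
#'
#' Advances one cell's cycle bookkeeping by `dt` hours using the engine's
#' area-linear growth schedule, with every growth increment either accepted
#' (`accept_growth = TRUE`, the isolated-cell limit) or rejected (a fully
#' jammed cell).  Emits the same S/M entry and division events the full
#' simulation would.  Mainly useful for inspecting the schedule; the Monte
#' Carlo engine applies the identical bookkeeping per accepted trial.
#'
#' @param population A `cell_population`.
#' @param cell Row index of the cell to advance.
#' @param params A [model_params()].
#' @param t Current time in hours.
#' @param dt Hours to advance.
#' @param accept_growth Whether growth/deformation increments are accepted.
#' @return List with `population` (possibly with the cell replaced by two
#'   daughters) and `events`.
#' @export
progress_cell_cycle <- function(population, cell, params, t = 0, dt = 1,
                                accept_growth = TRUE) {
  stopifnot(dt > 0)
  ep <- engine_params(params, attr(population, "domain_radius"))
  tt <- types_table(attr(population, "types"))
  res <- cpp_progress_cell(as_pop_matrix(population), cell, ep, tt, t, dt,
                           accept_growth)
  res$population <- new_population(res$population,
                                   attr(population, "types"),
                                   attr(population, "domain_radius"),
                                   attr(population, "density"))
  res$events <- as.data.frame(res$events)
  res
}
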