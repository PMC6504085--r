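#' Define a cell type
#'
#' A cell type carries a relative size (its interphase starting radius, in
#' units of one standard cell radius), the truncated-normal distribution of
#' cell-cycle lengths drawn at each birth, and the fraction of the initial
#' population seeded with this type.
#'
#' @param name Type name (used by cell-type identity pathways).
#' @param size Relative initial radius, dimensionless; default 1.
#' @param cycle_mean Mean cell-cycle length in hours (> 0).
#' @param cycle_sd Standard deviation of the cycle length in hours (>= 0).
#' @param proportion Fraction of the initial population in \[0, 1\].
#' @return An object of class `cell_type`.
#' @examples
#' type_a <- cell_type("A", cycle_mean = 12, cycle_sd = 4, proportion = 0.5)
#' @export
cell_type <- function(name, size = 1, cycle_mean = 24, cycle_sd = 4,
                      proportion = 1) {
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  stopifnot_scalar(size, "size", lower = 0, strict_lower = TRUE)
  stopifnot_scalar(cycle_mean, "cycle_mean", lower = 0, strict_lower = TRUE)
  stopifnot_scalar(cycle_sd, "cycle_sd", lower = 0)
  stopifnot_scalar(proportion, "proportion", lower = 0, upper = 1)
  structure(list(name = name, size = size, cycle_mean = cycle_mean,
                 cycle_sd = cycle_sd, proportion = proportion),
            class = "cell_type")
}

#' @export
print.cell_type <- function(x, ...) {
  cat(sprintf("<cell_type '%s'> size %.2f, cycle %.1f +/- %.1f h, %.0f%%\n",
              x$name, x$size, x$cycle_mean, x$cycle_sd, 100 * x$proportion))
  invisible(x)
}

check_cell_types <- function(types) {
  if (inherits(types, "cell_type")) types <- list(types)
  stopifnot(length(types) >= 1)
  for (ty in types) {
    if (!inherits(ty, "cell_type")) stop("all types must be cell_type objects")
  }
  p <- vapply(types, `[[`, numeric(1), "proportion")
  if (abs(sum(p) - 1) > 1e-8) {
    stop("cell type proportions must sum to 1 (got ", sum(p), ")")
  }
  nm <- vapply(types, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("cell type names must be unique")
  types
}

# vector-form type table handed to the C++ engine
types_table <- function(types) {
  types <- check_cell_types(types)
  list(size = vapply(types, `[[`, numeric(1), "size"),
       cycle_mean = vapply(types, `[[`, numeric(1), "cycle_mean"),
       cycle_sd = vapply(types, `[[`, numeric(1), "cycle_sd"),
       name = vapply(types, `[[`, character(1), "name"))
}

#' Cell model parameters
#'
#' Bundles the high-level run parameters (initial cell count, duration,
#' initial density) with the Monte Carlo mechanics constants.  Lengths are
#' in units of one standard cell radius, times in hours, energies in units
#' of kT.
#'
#' @param initial_num Initial number of cells (>= 1).
#' @param hours Simulated duration in hours (>= 0).
#' @param density Initial area fraction of the seeding disk in (0, 1).
#' @param boundary `"unbounded"` (default) or `"circular"`.  A circular
#'   boundary is a hard wall: any trial pushing a disk outside is rejected.
#' @param boundary_radius Radius of the circular wall; default (`NULL`) is
#'   the seeding-disk radius.
#' @param epsilon_rep Repulsion energy scale of the quadratic overlap
#'   penalty (kT).
#' @param epsilon_adh Depth of the square adhesion well (kT).
#' @param adhesion_range Width of the adhesion well beyond contact.
#' @param mc_steps_per_hour Monte Carlo sweeps per simulated hour.
#' @param max_migration Maximum displacement per migration trial.
#' @param mitosis_duration Duration of mitosis (dumbbell stage) in hours.
#' @param phase_thresholds Area ratios (relative to the type's resting
#'   area) at which a cell enters S, G2 and M.
#' @param record_every Hours between recorded snapshots.
#' @param radius_factor Neighborhood radius (multiple of the cell radius)
#'   used for local density.
#' @param density_grid Quadrature resolution `c(n_r, n_theta)` for local
#'   density.
#' @param seed RNG seed for [run_cell_model()]; `NULL` uses the current
#'   RNG state.
#' @return An object of class `model_params`.
#' @examples
#' params <- model_params(100, 72, 0.01)
#' @export
model_params <- function(initial_num, hours, density,
                         boundary = c("unbounded", "circular"),
                         boundary_radius = NULL,
                         epsilon_rep = 2000, epsilon_adh = 0.1,
                         adhesion_range = 0.3, mc_steps_per_hour = 10,
                         max_migration = 0.5, mitosis_duration = 1,
                         phase_thresholds = c(1.3, 1.7, 2.0),
                         record_every = 1, radius_factor = 3,
                         density_grid = c(16, 64), seed = NULL) {
  boundary <- match.arg(boundary)
  stopifnot_scalar(initial_num, "initial_num", lower = 1)
  stopifnot_scalar(hours, "hours", lower = 0)
  stopifnot_scalar(density, "density", lower = 0, upper = 1,
                   strict_lower = TRUE, strict_upper = TRUE)
  stopifnot_scalar(epsilon_rep, "epsilon_rep", lower = 0)
  stopifnot_scalar(epsilon_adh, "epsilon_adh", lower = 0)
  stopifnot_scalar(adhesion_range, "adhesion_range", lower = 0)
  stopifnot_scalar(mc_steps_per_hour, "mc_steps_per_hour", lower = 1)
  stopifnot_scalar(max_migration, "max_migration", lower = 0)
  stopifnot_scalar(mitosis_duration, "mitosis_duration", lower = 0,
                   strict_lower = TRUE)
  stopifnot(length(phase_thresholds) == 3,
            all(diff(phase_thresholds) > 0),
            phase_thresholds[1] > 1)
  stopifnot_scalar(radius_factor, "radius_factor", lower = 1,
                   strict_lower = TRUE)
  if (!is.null(boundary_radius)) {
    stopifnot_scalar(boundary_radius, "boundary_radius", lower = 0,
                     strict_lower = TRUE)
  }
  structure(list(initial_num = as.integer(initial_num), hours = hours,
                 density = density, boundary = boundary,
                 boundary_radius = boundary_radius,
                 epsilon_rep = epsilon_rep, epsilon_adh = epsilon_adh,
                 adhesion_range = adhesion_range,
                 mc_steps_per_hour = as.integer(mc_steps_per_hour),
                 max_migration = max_migration,
                 mitosis_duration = mitosis_duration,
                 phase_thresholds = phase_thresholds,
                 record_every = record_every,
                 radius_factor = radius_factor,
                 density_grid = as.integer(density_grid),
                 seed = seed),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf(paste0("<model_params> %d cells, %.0f h, density %.3g, ",
                     "%s domain\n"),
              x$initial_num, x$hours, x$density, x$boundary))
  invisible(x)
}

# flat parameter list handed to the C++ engine; the wall radius is resolved
# against the population's seeding disk
engine_params <- function(params, domain_radius = NULL) {
  wall <- -1
  if (params$boundary == "circular") {
    wall <- params$boundary_radius %||% domain_radius
    if (is.null(wall)) stop("circular boundary needs a radius")
  }
  list(epsilon_rep = params$epsilon_rep, epsilon_adh = params$epsilon_adh,
       adhesion_range = params$adhesion_range,
       max_migration = params$max_migration,
       mitosis_duration = params$mitosis_duration,
       mc_steps_per_hour = params$mc_steps_per_hour,
       boundary_radius = wall,
       phase_thresholds = params$phase_thresholds)
}
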