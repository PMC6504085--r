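#' Metropolis acceptance probability
#'
#' @param delta_e Energy change of a trial move (kT units); may be a vector.
#' @return `min(1, exp(-delta_e))`, elementwise.
#' @examples
#' accept_probability(c(0, -5, log(2)))
#' @export
accept_probability <- function(delta_e) {
  stopifnot(is.numeric(delta_e), all(is.finite(delta_e)))
  pmin(1, exp(-delta_e))
}

#' Pairwise interaction energy between two cells
#'
#' With `d` the center distance of two disks and `s` the sum of their radii,
#' each disk pair contributes `epsilon_rep * ((s - d) / s)^2` when
#' overlapping (`d < s`), `-epsilon_adh` inside the adhesion well
#' (`s <= d < s + adhesion_range`) and 0 otherwise.  A mitotic cell
#' contributes its two dumbbell disks; the cell pair energy is the sum over
#' disk pairs.
#'
#' @param population A `cell_population` (or snapshot matrix).
#' @param i,j Row indices of the two cells.
#' @param params A [model_params()].
#' @return Energy in kT (dimensionless).
#' @export
pair_potential <- function(population, i, j, params) {
  stopifnot(i != j)
  cpp_pair_energy(as_pop_matrix(population), i, j,
                  engine_params(params, attr(population, "domain_radius")),
                  types_table(attr(population, "types")))
}

#' Total interaction energy of a population
#'
#' Sum of [pair_potential()] over unordered cell pairs.
#'
#' @inheritParams pair_potential
#' @return Energy in kT.
#' @export
total_energy <- function(population, params) {
  cpp_total_energy(as_pop_matrix(population),
                   engine_params(params, attr(population, "domain_radius")),
                   types_table(attr(population, "types")))
}

as_pop_matrix <- function(population) {
  m <- unclass(population)
  stopifnot(is.matrix(m), ncol(m) == length(POP_COLS))
  m
}
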