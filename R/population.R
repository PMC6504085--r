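# population matrix column layout shared with the C++ engine
POP_COLS <- c("id", "type", "x", "y", "radius", "phase", "axis",
              "separation", "cycle_length", "birth_time", "enter_S",
              "enter_M", "m_entry", "growth_area")

PHASE_LEVELS <- c("G1", "S", "G2", "M")

new_population <- function(mat, types, domain_radius, density) {
  colnames(mat) <- POP_COLS
  structure(mat, types = types, domain_radius = domain_radius,
            density = density, class = c("cell_population", "matrix"))
}

#' @export
print.cell_population <- function(x, ...) {
  cat(sprintf("<cell_population> %d cells, seeding-disk radius %.2f\n",
              nrow(x), attr(x, "domain_radius")))
  invisible(x)
}

#' Coerce a cell population to a data frame
#'
#' @param x A `cell_population`.
#' @param ... Unused.
#' @return A data frame with one row per cell; `type` and `phase` are
#'   translated to their names.
#' @export
as.data.frame.cell_population <- function(x, ...) {
  population_df(unclass(x), attr(x, "types"))
}

population_df <- function(mat, types) {
  df <- as.data.frame(mat[, , drop = FALSE])
  colnames(df) <- POP_COLS
  tn <- vapply(types, `[[`, character(1), "name")
  df$type <- tn[df$type]
  df$phase <- PHASE_LEVELS[df$phase]
  df
}

# number of cells by type under largest-remainder rounding
type_counts <- function(types, n) {
  p <- vapply(types, `[[`, numeric(1), "proportion")
  base <- floor(p * n)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- p * n - base
    take <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base[take] <- base[take] + 1
  }
  as.integer(base)
}

# area and radius of the seeding disk: total resting cell area / density
seeding_disk <- function(params, types) {
  types <- check_cell_types(types)
  counts <- type_counts(types, params$initial_num)
  r0 <- vapply(types, `[[`, numeric(1), "size")
  area <- sum(counts * pi * r0^2) / params$density
  list(area = area, radius = sqrt(area / pi), counts = counts)
}

#' Seed an initial cell population
#'
#' Places `initial_num` non-overlapping cells uniformly (dart throwing with
#' rejection) inside a disk whose area is the total resting cell area
#' divided by `density`, so the realized initial area fraction equals the
#' `density` argument by construction.  Types are assigned by proportion
#' with largest-remainder rounding.  Each cell receives a fresh cycle
#' length and a uniformly random progress through interphase (with the
#' matching radius and phase), so the population is desynchronized at t = 0.
#'
#' @param params A [model_params()].
#' @param types A [cell_type()] or list of them; proportions must sum to 1.
#' @return A `cell_population` matrix with attributes `types`,
#'   `domain_radius` and `density`.
#' @examples
#' pop <- seed_population(model_params(20, 10, 0.01), cell_type("A"))
#' @export
seed_population <- function(params, types) {
  stopifnot(inherits(params, "model_params"))
  if (inherits(types, "cell_type")) types <- list(types)
  types <- check_cell_types(types)
  disk <- seeding_disk(params, types)
  n <- params$initial_num

  type_idx <- rep(seq_along(types), disk$counts)
  mat <- matrix(0, nrow = n, ncol = length(POP_COLS))
  colnames(mat) <- POP_COLS
  max_tries <- 2000L

  for (i in seq_len(n)) {
    ty <- types[[type_idx[i]]]
    r0 <- ty$size
    cl <- sample_cycle_length(ty, 1, params$mitosis_duration)
    u <- runif(1)                       # progress through interphase
    r <- r0 * sqrt(1 + u)
    a <- 1 + u                          # area ratio
    th <- params$phase_thresholds
    phase <- if (a < th[1]) 1L else if (a < th[2]) 2L else 3L
    interphase <- cl - params$mitosis_duration
    birth <- -u * interphase
    enter_s <- if (phase >= 2) birth + (th[1] - 1) * interphase else NA_real_

    placed <- FALSE
    for (try in seq_len(max_tries)) {
      ang <- 2 * pi * runif(1)
      rad <- disk$radius * sqrt(runif(1))
      x <- rad * cos(ang); y <- rad * sin(ang)
      if (i == 1) { placed <- TRUE } else {
        prev <- mat[seq_len(i - 1), , drop = FALSE]
        d2 <- (prev[, "x"] - x)^2 + (prev[, "y"] - y)^2
        placed <- all(d2 > (prev[, "radius"] + r)^2)
      }
      if (placed) break
    }
    if (!placed) {
      stop("seed_population: could not place cell ", i, " after ",
           max_tries, " attempts; initial density ", params$density,
           " is too high to pack non-overlapping cells", call. = FALSE)
    }
    mat[i, ] <- c(i, type_idx[i], x, y, r, phase, 0, 0, cl, birth,
                  enter_s, NA_real_, NA_real_, 0)
  }
  new_population(mat, types, disk$radius, params$density)
}

#' Realized seeding density
#'
#' Total resting cell area divided by the seeding-disk area; equals the
#' `density` argument of [model_params()] by construction.
#'
#' @param population A `cell_population`.
#' @return Area fraction in (0, 1).
#' @export
realized_density <- function(population) {
  types <- attr(population, "types")
  r0 <- vapply(types, `[[`, numeric(1), "size")
  m <- unclass(population)
  sum(pi * r0[m[, "type"]]^2) / (pi * attr(population, "domain_radius")^2)
}
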