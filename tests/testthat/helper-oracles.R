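# independent pure-R oracles, kept free of the package's C++ code paths

# disks making up a cell row of the population matrix
oracle_disks <- function(row, r0) {
  if (row[["phase"]] == 4) {
    hx <- 0.5 * row[["separation"]] * cos(row[["axis"]])
    hy <- 0.5 * row[["separation"]] * sin(row[["axis"]])
    list(x = row[["x"]] + c(hx, -hx), y = row[["y"]] + c(hy, -hy),
         r = c(r0, r0))
  } else {
    list(x = row[["x"]], y = row[["y"]], r = row[["radius"]])
  }
}

oracle_disk_energy <- function(d, s, eps_rep, eps_adh, adh_range) {
  if (d < s) eps_rep * ((s - d) / s)^2
  else if (d < s + adh_range) -eps_adh
  else 0
}

oracle_pair_energy <- function(row_a, row_b, r0a, r0b, params) {
  da <- oracle_disks(row_a, r0a); db <- oracle_disks(row_b, r0b)
  e <- 0
  for (i in seq_along(da$r)) for (j in seq_along(db$r)) {
    d <- sqrt((da$x[i] - db$x[j])^2 + (da$y[i] - db$y[j])^2)
    e <- e + oracle_disk_energy(d, da$r[i] + db$r[j], params$epsilon_rep,
                                params$epsilon_adh, params$adhesion_range)
  }
  e
}

oracle_total_energy <- function(population, params) {
  types <- attr(population, "types")
  r0 <- vapply(types, `[[`, numeric(1), "size")
  m <- unclass(population)
  n <- nrow(m)
  e <- 0
  if (n < 2) return(0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    e <- e + oracle_pair_energy(m[i, ], m[j, ], r0[m[i, "type"]],
                                r0[m[j, "type"]], params)
  }
  e
}

# Monte Carlo area oracle: fraction of the annulus (r, f*r] around (cx, cy)
# covered by the given disks
oracle_annulus_coverage <- function(cx, cy, r, f, disks, n = 1e6) {
  rho <- sqrt(runif(n, r^2, (f * r)^2))
  th <- runif(n, 0, 2 * pi)
  px <- cx + rho * cos(th); py <- cy + rho * sin(th)
  covered <- rep(FALSE, n)
  for (k in seq_len(nrow(disks))) {
    covered <- covered |
      ((px - disks[k, 1])^2 + (py - disks[k, 2])^2 <= disks[k, 3]^2)
  }
  mean(covered)
}

# brute-force evaluation of the activity -> mean expression map
oracle_mean_expression <- function(P, pathways, mode) {
  if (mode == "bulk") {
    P <- matrix(rowMeans(P), ncol = 1)
  }
  genes <- unique(unlist(lapply(pathways, `[[`, "genes")))
  out <- matrix(NA_real_, length(genes), ncol(P),
                dimnames = list(genes, NULL))
  for (g in seq_along(genes)) {
    for (s in seq_len(ncol(P))) {
      vals <- c()
      for (k in seq_along(pathways)) {
        pw <- pathways[[k]]
        if (genes[g] %in% pw$genes) {
          vals <- c(vals, P[k, s] * pw$gmax[[genes[g]]] +
                            (1 - P[k, s]) * pw$gmin[[genes[g]]])
        }
      }
      out[g, s] <- mean(vals)
    }
  }
  out
}

# random calibrated pathways + activity matrix for Eq-1 style tests
random_expression_instance <- function(n_pathways, n_genes, n_cells) {
  gene_pool <- paste0("g", seq_len(n_genes))
  pathways <- lapply(seq_len(n_pathways), function(k) {
    genes <- sample(gene_pool, sample(2:n_genes, 1))
    pw <- pathway(paste0("pw", k), genes, function(...) 0)
    m <- runif(length(genes), 0, 20)
    w <- runif(length(genes), 0, 6)
    pw$gmin <- stats::setNames(pmax(0, m - w / 2), genes)
    pw$gmax <- stats::setNames(m + w / 2, genes)
    pw
  })
  P <- matrix(runif(n_pathways * n_cells), n_pathways, n_cells)
  list(pathways = pathways, P = P)
}

# construction with exactly one energy-changing trial kind: cell 1 has one
# scheduled growth increment due, cell 2 is a frozen neighbor, migration is
# disabled.  Every sweep from the same state attempts cell-1 growth with
# probability 1/4 per trial, so the per-sweep acceptance probability has
# the closed form 1 - (1 - p/4)^2 with p = min(1, exp(-dE)).
metropolis_setup <- function(gap = 0.186) {
  params <- model_params(2, 1, 0.01, max_migration = 0)
  ty <- cell_type("A", cycle_mean = 13, cycle_sd = 0)
  mat <- matrix(0, 2, length(cellgex:::POP_COLS))
  colnames(mat) <- cellgex:::POP_COLS
  #                id type  x             y  r        ph ax sep cl  birth
  mat[1, ] <- c(1, 1, 0, 0, 1, 1, 0, 0, 13, -6, NA, NA, NA, 0)
  mat[2, ] <- c(2, 1, 1 + sqrt(2) + gap, 0, sqrt(2), 3, 0, 0, 13, -100,
                NA, NA, NA, 0)
  pop <- cellgex:::new_population(mat, list(ty), domain_radius = 50,
                                  density = 0.01)
  r_new <- sqrt(1.5)                      # target area at t = 0 is 1.5 pi
  after <- pop; after[1, "radius"] <- r_new
  dE <- oracle_pair_energy(unclass(after)[1, ], unclass(after)[2, ], 1, 1,
                           params) -
        oracle_pair_energy(unclass(pop)[1, ], unclass(pop)[2, ], 1, 1,
                           params)
  list(pop = pop, params = params, dE = dE, r_new = r_new)
}

metropolis_acceptance_rate <- function(setup, n_sweeps) {
  acc <- 0L
  for (i in seq_len(n_sweeps)) {
    res <- monte_carlo_step(setup$pop, setup$params, t = 0)
    if (res$population[1, "radius"] > 1) acc <- acc + 1L
  }
  acc / n_sweeps
}

# random population matrix (including mitotic dumbbells) for energy oracles
random_population <- function(n, box = 10, p_mitotic = 0.2,
                              type = cell_type("A", cycle_mean = 12,
                                               cycle_sd = 0)) {
  mat <- matrix(0, n, length(cellgex:::POP_COLS))
  colnames(mat) <- cellgex:::POP_COLS
  for (i in seq_len(n)) {
    mitotic <- runif(1) < p_mitotic
    mat[i, ] <- c(i, 1, runif(1, -box, box), runif(1, -box, box),
                  if (mitotic) sqrt(2) else runif(1, 1, sqrt(2)),
                  if (mitotic) 4 else sample(1:3, 1),
                  runif(1, 0, 2 * pi), if (mitotic) runif(1, 0, 2) else 0,
                  12, 0, NA, NA, if (mitotic) 0 else NA, 0)
  }
  cellgex:::new_population(mat, list(type), domain_radius = box * 2,
                           density = 0.1)
}
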