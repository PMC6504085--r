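test_that("pair potential matches its closed form", {
  params <- model_params(2, 1, 0.01, epsilon_rep = 4, epsilon_adh = 0.1,
                         adhesion_range = 0.3)
  two_cells <- function(d) {
    p <- random_population(2, p_mitotic = 0)
    p[1, c("x", "y", "radius")] <- c(0, 0, 1)
    p[2, c("x", "y", "radius")] <- c(d, 0, 1)
    p
  }
  expect_identical(pair_potential(two_cells(3.3), 1, 2, params), 0)
  expect_identical(pair_potential(two_cells(2), 1, 2, params), -0.1)
  expect_equal(pair_potential(two_cells(1), 1, 2, params), 1.0,
               tolerance = 1e-12)   # d = s/2: 4 * (1/2)^2
})

test_that("accept_probability implements the Metropolis rule", {
  expect_identical(accept_probability(0), 1)
  expect_identical(accept_probability(-5), 1)
  expect_equal(accept_probability(log(2)), 0.5, tolerance = 1e-15)
  expect_error(accept_probability(Inf))
})

test_that("engine acceptance follows exp(-dE) for an uphill trial", {
  setup <- metropolis_setup()
  expect_gt(setup$dE, 0)
  p <- exp(-setup$dE)
  expected <- 1 - (1 - p / 4)^2
  set.seed(11)
  n <- 4000
  rate <- metropolis_acceptance_rate(setup, n)
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(rate - expected), 3 * se)
})

test_that("downhill growth of an isolated cell is always accepted", {
  setup <- metropolis_setup(gap = 5)      # neighbor out of range: dE = 0
  expect_identical(setup$dE, 0)
  set.seed(12)
  rate <- metropolis_acceptance_rate(setup, 500)
  expect_equal(rate, 1 - (1 - 1 / 4)^2, tolerance = 0.08)
})

test_that("C++ total energy matches the pure-R oracle (with dumbbells)", {
  params <- model_params(10, 1, 0.01)
  set.seed(13)
  for (i in 1:5) {
    pop <- random_population(30, box = 6, p_mitotic = 0.25)
    expect_equal(total_energy(pop, params), oracle_total_energy(pop, params),
                 tolerance = 1e-9)
  }
})

test_that("incremental energy tracking matches brute force over sweeps", {
  set.seed(14)
  params <- model_params(40, 3, 0.3)
  pop <- seed_population(params, cell_type("A", cycle_mean = 6,
                                           cycle_sd = 1))
  energy <- total_energy(pop, params)
  t <- 0
  for (s in 1:30) {
    res <- monte_carlo_step(pop, params, t = t, energy = energy)
    pop <- res$population; energy <- res$energy; t <- res$time
    expect_lt(abs(energy - total_energy(pop, params)), 1e-8)
  }
  expect_lt(abs(energy - oracle_total_energy(pop, params)), 1e-8)
  expect_gte(nrow(pop), 40)               # no cell death
})
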