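# fresh G1 cell at a known state, for deterministic schedule checks
fresh_cell_population <- function(cycle_length = 12) {
  ty <- cell_type("A", cycle_mean = cycle_length, cycle_sd = 0)
  mat <- matrix(c(1, 1, 0, 0, 1, 1, 0, 0, cycle_length, 0, NA, NA, NA, 0),
                nrow = 1)
  colnames(mat) <- cellgex:::POP_COLS
  cellgex:::new_population(mat, list(ty), domain_radius = 20,
                           density = 0.01)
}

test_that("an unimpeded cell follows the phase schedule and divides on time", {
  params <- model_params(1, 20, 0.01, mitosis_duration = 1)
  pop <- fresh_cell_population(cycle_length = 12)
  set.seed(21)
  res <- progress_cell_cycle(pop, 1, params, t = 0, dt = 12.3)
  ev <- res$events
  step <- 1 / params$mc_steps_per_hour
  # area-linear schedule over 11 h of interphase: S at 0.3, G2 at 0.7
  expect_equal(ev$time[ev$event == "enter_S"], 0.3 * 11,
               tolerance = 2 * step)
  expect_equal(ev$time[ev$event == "enter_M"], 11, tolerance = 2 * step)
  expect_equal(ev$time[ev$event == "division"], 12, tolerance = 2 * step)
  expect_identical(ev$event[order(ev$time)],
                   c("enter_S", "enter_M", "division"))
  # division geometry: two fresh radius-r0 daughters tangent along the axis
  d <- as.data.frame(res$population)
  expect_identical(nrow(d), 2L)
  # daughter 1 keeps progressing after the division for the remaining
  # ~0.3 h of the call, so allow its schedule-worth of growth
  expect_equal(d$radius, c(1, 1), tolerance = 0.02)
  expect_equal(sqrt(diff(d$x)^2 + diff(d$y)^2), 2, tolerance = 1e-12)
  expect_true(all(d$phase == "G1"))
  expect_equal(d$birth_time, rep(ev$time[ev$event == "division"], 2),
               tolerance = 1e-12)
})

test_that("a fully jammed cell never progresses", {
  params <- model_params(1, 20, 0.01)
  pop <- fresh_cell_population()
  res <- progress_cell_cycle(pop, 1, params, t = 0, dt = 13,
                             accept_growth = FALSE)
  expect_identical(nrow(res$events), 0L)
  expect_equal(unname(res$population[1, "radius"]), 1,
               tolerance = 1e-12)
})

test_that("runs are bitwise reproducible from the seed", {
  params <- model_params(15, 6, 0.02, seed = 99)
  ty <- cell_type("A", cycle_mean = 8, cycle_sd = 2)
  t1 <- run_cell_model(params, ty)
  t2 <- run_cell_model(params, ty)
  expect_identical(t1$snapshots, t2$snapshots)
  expect_identical(t1$events, t2$events)
})

test_that("hours = 0 yields exactly the initial snapshot", {
  traj <- run_cell_model(model_params(10, 0, 0.01, seed = 1),
                         cell_type("A"))
  expect_identical(length(traj$times), 1L)
  expect_identical(traj$times, 0)
  expect_identical(nrow(traj$snapshots[[1]]), 10L)
})

test_that("population size never decreases and events are consistent", {
  traj <- fx_sparse_traj()
  n <- vapply(traj$snapshots, nrow, integer(1))
  expect_true(all(diff(n) >= 0))
  n_div <- sum(traj$events$event == "division")
  expect_identical(n[length(n)], n[1] + n_div)  # two daughters per division
  expect_lte(max(table(traj$events$cell_id[
    traj$events$event == "enter_S"])), 1)       # one S entry per cell
})

test_that("sparse populations at least double every 1.25 cycle lengths", {
  traj <- fx_sparse_traj()                      # 12 h type, 3T = 36 h
  n <- vapply(traj$snapshots, nrow, integer(1))
  at <- function(t) n[which.min(abs(traj$times - t))]
  expect_gte(at(15), 2 * at(0))
  expect_gte(at(30), 2 * at(15))
})

test_that("realized division intervals recover the cycle distribution", {
  traj <- fx_sparse_traj()
  iv <- division_intervals(traj, "A", max_birth = 36)
  expect_gt(length(iv), 200)
  mom <- cellgex:::cycle_length_moments(traj$types[[1]])
  lag <- 2.5 / traj$params$mc_steps_per_hour   # scheduler latency
  expect_lt(abs(mean(iv) - (mom[["mean"]] + lag)),
            3 * sd(iv) / sqrt(length(iv)))
  expect_lt(abs(sd(iv) - mom[["sd"]]), 3 * sd(iv) / sqrt(2 * length(iv)))
})

test_that("local density matches geometry and the Monte Carlo oracle", {
  pop <- random_population(2, p_mitotic = 0)
  pop[1, c("x", "y", "radius")] <- c(0, 0, 1)
  # isolated cell: move the neighbor far away
  pop[2, c("x", "y", "radius")] <- c(100, 0, 1)
  expect_identical(local_density(pop, 1, radius_factor = 3), 0)
  # annulus entirely inside a giant neighbor disk
  pop[2, c("x", "y", "radius")] <- c(0, 0, 50)
  expect_identical(local_density(pop, 1, radius_factor = 3), 1)
  # tangent unit neighbor vs 1e6-point Monte Carlo area oracle
  pop[2, c("x", "y", "radius")] <- c(2, 0, 1)
  set.seed(22)
  mc <- oracle_annulus_coverage(0, 0, 1, 3, matrix(c(2, 0, 1), 1))
  expect_equal(local_density(pop, 1, radius_factor = 3), mc,
               tolerance = 1e-2)
  expect_error(local_density(pop, 1, radius_factor = 1), "radius_factor")
})

test_that("bounded runs crowd up and divisions slow down", {
  traj <- fx_bulk()$trajectory
  ld <- vapply(traj$snapshots, function(s) mean(s$local_density),
               numeric(1))
  # non-decreasing within sampling noise: compare 12-h block means
  blocks <- tapply(ld, (seq_along(ld) - 1) %/% 12, mean)
  expect_true(all(diff(blocks) > -0.02))
  expect_gt(ld[length(ld)], ld[1])
  # wall confines the population
  final <- traj$snapshots[[length(traj$snapshots)]]
  expect_true(all(sqrt(final$x^2 + final$y^2) <= traj$domain_radius + 1e-9))
  # per-cell division rate drops between the first and last quarter
  n <- vapply(traj$snapshots, nrow, numeric(1))
  ev <- traj$events[traj$events$event == "division", ]
  tmax <- max(traj$times)
  early <- sum(ev$time <= tmax / 4) / mean(n[traj$times <= tmax / 4])
  late <- sum(ev$time > 3 * tmax / 4) / mean(n[traj$times > 3 * tmax / 4])
  expect_lt(late, early)
})
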