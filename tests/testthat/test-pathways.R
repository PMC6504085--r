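test_that("phase-transition activity is binary and windowed", {
  traj <- fx_sparse_traj()
  ev <- traj$events
  # S-entering cells live long enough to query both inside and outside
  # the event window (M-entering cells divide away within an hour)
  es <- ev[ev$event == "enter_S" & ev$time > 5 & ev$time < 40, ]
  # keep cells whose (implied) cycle leaves them alive 2.5 h past S entry
  gap <- es$time - es$birth_time          # 0.3 * interphase
  es <- es[gap / 0.3 + 1 - gap > 4, ]
  expect_gt(nrow(es), 10)
  e1 <- es[1, ]
  t_in <- traj$times[which(traj$times >= e1$time)[1]]
  if (t_in - e1$time <= 1) {
    expect_identical(
      activity_phase_transition(traj, e1$cell_id, t_in, "S", window = 1), 1)
  }
  t_out <- traj$times[which(traj$times > e1$time + 1.5)[1]]
  expect_identical(
    activity_phase_transition(traj, e1$cell_id, t_out, "S", window = 1), 0)
  # binary over a whole snapshot, for both rules
  snap <- snapshot_at(traj, 24)
  expect_true(all(activity_phase_transition(traj, snap$id, 24, "S")
                  %in% c(0, 1)))
  expect_true(all(activity_phase_transition(traj, snap$id, 24, "M")
                  %in% c(0, 1)))
  expect_error(activity_phase_transition(traj, 999999, 24, "S"),
               "unknown cell id")
})

test_that("contact inhibition delegates to stored local density", {
  traj <- fx_small_traj()
  snap <- snapshot_at(traj, 6)
  expect_identical(activity_contact_inhibition(traj, snap$id, 6),
                   snap$local_density)
})

test_that("growth rate is high when sparse, zero in mitosis", {
  traj <- fx_sparse_traj()
  snap <- snapshot_at(traj, 10)
  interphase <- snap[snap$phase != "M", ]
  expect_gt(mean(interphase$growth_rate), 0.8)
  mphase <- snap[snap$phase == "M", ]
  if (nrow(mphase) > 0) {
    expect_identical(activity_growth_rate(traj, mphase$id, 10),
                     rep(0, nrow(mphase)))
  }
  # jammed cells in the saturated bounded run grow much slower
  bulk <- fx_bulk()$trajectory
  late <- snapshot_at(bulk, max(bulk$times))
  expect_lt(mean(late$growth_rate), 0.3)
})

test_that("cell-type activity is a one-hot partition", {
  traj <- fx_small_traj()
  snap <- snapshot_at(traj, 4)
  pa <- activity_cell_type(traj, snap$id, 4, "A")
  pb <- activity_cell_type(traj, snap$id, 4, "B")
  expect_true(all(pa %in% c(0, 1)))
  expect_identical(pa + pb, rep(1, nrow(snap)))
  expect_identical(pa, as.numeric(snap$type == "A"))
  expect_error(activity_cell_type(traj, snap$id, 4, "Z"),
               "unknown cell type")
})

test_that("all activity rules stay in [0, 1] across randomized queries", {
  traj <- fx_small_traj()
  pws <- fx_small_pathways()
  set.seed(31)
  for (t in sample(traj$times, 5)) {
    snap <- snapshot_at(traj, t)
    ids <- sample(snap$id, min(10, nrow(snap)))
    P <- pathway_activity(traj, pws, ids, t)
    expect_true(all(P >= 0 & P <= 1))
    expect_identical(dim(P), c(3L, length(ids)))
  }
})

test_that("distribution calibration matches its sampling oracle", {
  genes <- paste0("g", 1:10000)
  pw <- pathway("big", genes, function(...) 0)
  cal <- calibrate_from_distribution(pw, lambda = 20, stddev = 2, seed = 8)
  expect_true(all(cal$gmin >= 0))
  expect_true(all(cal$gmin <= cal$gmax))
  # oracle for the clipped construction (clipping shifts the midpoint up)
  set.seed(32)
  m <- rexp(1e5, 1 / 20); w <- abs(rnorm(1e5, 0, 2))
  mid_oracle <- (pmax(0, m - w / 2) + m + w / 2) / 2
  mid <- (cal$gmin + cal$gmax) / 2
  se <- sqrt(sd(mid)^2 / length(mid) + sd(mid_oracle)^2 / length(mid_oracle))
  expect_lt(abs(mean(mid) - mean(mid_oracle)), 3 * se)

  # zero width collapses the range
  cal0 <- calibrate_from_distribution(pw, lambda = 20, stddev = 0, seed = 8)
  expect_identical(cal0$gmin, cal0$gmax)

  # same seed, same ranges
  cal2 <- calibrate_from_distribution(pw, lambda = 20, stddev = 2, seed = 8)
  expect_identical(cal$gmin, cal2$gmin)
  expect_identical(cal$gmax, cal2$gmax)
})

test_that("reference calibration takes 5th/95th percentile per gene row", {
  ref <- matrix(c(rep(7, 100), 1:100), nrow = 2, byrow = TRUE,
                dimnames = list(c("const", "ramp"), NULL))
  pw <- pathway("p", c("const", "ramp"), function(...) 0)
  cal <- calibrate_from_reference(pw, ref)
  expect_equal(unname(cal$gmin[["const"]]), 7)
  expect_equal(unname(cal$gmax[["const"]]), 7)
  expect_equal(unname(cal$gmin[["ramp"]]), 5.95, tolerance = 1e-12)
  expect_equal(unname(cal$gmax[["ramp"]]), 95.05, tolerance = 1e-12)
  pw2 <- pathway("p2", c("const", "absent"), function(...) 0)
  expect_error(calibrate_from_reference(pw2, ref), "absent")
})

test_that("pathway constructor validates inputs", {
  expect_error(pathway("p", c("a", "a"), function(...) 0), "unique")
  expect_error(pathway("p", character(0), function(...) 0))
})
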