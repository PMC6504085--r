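test_that("cell sampling is uniform-without-replacement with clamping", {
  traj <- fx_small_traj()
  snap <- snapshot_at(traj, 0)
  ids <- sample_cells(traj, 0, nrow(snap))
  expect_setequal(ids, snap$id)
  expect_identical(anyDuplicated(ids), 0L)
  expect_warning(short <- sample_cells(traj, 0, nrow(snap) + 50),
                 "fewer than n_cells")
  expect_setequal(short, snap$id)
  set.seed(41); a <- sample_cells(traj, 12, 5)
  set.seed(41); b <- sample_cells(traj, 12, 5)
  expect_identical(a, b)
  expect_error(sample_cells(traj, 3.14, 5), "no snapshot")
})

test_that("mean expression matches hand evaluations", {
  pw <- pathway("p", "g1", function(...) 0)
  pw$gmin <- c(g1 = 2); pw$gmax <- c(g1 = 10)
  P0 <- matrix(0, 1, 4); P1 <- matrix(1, 1, 4)
  expect_equal(unname(mean_expression(P0, list(pw), "bulk")["g1", 1]), 2)
  expect_equal(unname(mean_expression(P1, list(pw), "bulk")["g1", 1]), 10)
  # one gene in two pathways, activities 0.2 / 0.8, range (0, 10) in both
  pwa <- pathway("a", "g", function(...) 0)
  pwa$gmin <- c(g = 0); pwa$gmax <- c(g = 10)
  pwb <- pathway("b", "g", function(...) 0)
  pwb$gmin <- c(g = 0); pwb$gmax <- c(g = 10)
  P <- matrix(c(0.2, 0.8), 2, 1)
  expect_equal(unname(mean_expression(P, list(pwa, pwb), "bulk")["g", 1]),
               mean(c(2, 8)), tolerance = 1e-15)
})

test_that("mean expression matches the brute-force oracle", {
  set.seed(42)
  for (rep in 1:10) {
    inst <- random_expression_instance(sample(1:5, 1), sample(2:20, 1),
                                       sample(1:50, 1))
    for (mode in c("bulk", "single_cell")) {
      got <- mean_expression(inst$P, inst$pathways, mode)
      want <- oracle_mean_expression(inst$P, inst$pathways, mode)
      expect_equal(unname(got), unname(want), tolerance = 1e-12)
      expect_identical(rownames(got), rownames(want))
    }
  }
})

test_that("bulk equals the per-gene average of single-cell columns", {
  set.seed(43)
  inst <- random_expression_instance(3, 10, 20)
  bulk <- mean_expression(inst$P, inst$pathways, "bulk")
  sc <- mean_expression(inst$P, inst$pathways, "single_cell")
  expect_equal(unname(bulk[, 1]), unname(rowMeans(sc)), tolerance = 1e-12)
})

test_that("mean expression respects bounds and monotonicity", {
  set.seed(44)
  inst <- random_expression_instance(4, 12, 30)
  m <- mean_expression(inst$P, inst$pathways, "single_cell")
  for (g in rownames(m)) {
    in_pw <- Filter(function(pw) g %in% pw$genes, inst$pathways)
    lo <- min(vapply(in_pw, function(pw) pw$gmin[[g]], numeric(1)))
    hi <- max(vapply(in_pw, function(pw) pw$gmax[[g]], numeric(1)))
    expect_true(all(m[g, ] >= lo - 1e-12 & m[g, ] <= hi + 1e-12))
  }
  # raising one pathway's activity never lowers any gene
  P2 <- inst$P; P2[2, ] <- pmin(1, P2[2, ] + 0.1)
  m2 <- mean_expression(P2, inst$pathways, "single_cell")
  expect_true(all(m2 - m >= -1e-12))
  # a custom combiner is honored
  mx <- mean_expression(inst$P, inst$pathways, "single_cell", combine = max)
  expect_true(all(mx - m >= -1e-12))
})

test_that("unannotated genes are an error", {
  pw <- pathway("p", "g1", function(...) 0)
  expect_error(mean_expression(matrix(0, 1, 1), list(pw), "bulk"),
               "not calibrated")
})

test_that("microarray noise is mean-zero Gaussian with the stated sd", {
  m <- matrix(5, 100, 100)
  expect_identical(noise_microarray(m, 0), m)
  set.seed(45)
  resid <- noise_microarray(m, 0.25) - m
  expect_lt(abs(var(as.vector(resid)) - 0.25^2), 0.05 * 0.25^2)
  expect_lt(abs(mean(resid)), 3 * 0.25 / 100)
})

test_that("bulk RNA-seq counts match the NB closed forms", {
  g <- matrix(c(2, 5, 8, 3), 4, 1, dimnames = list(paste0("g", 1:4), "s"))
  a <- g / sum(g)
  lib <- 5e4
  set.seed(46)
  reps <- vapply(1:2000, function(i)
    noise_bulk_rnaseq(g, lib, 0.1)[, 1], numeric(4))
  mu <- lib * a[, 1]
  se <- sqrt((mu + 0.1 * mu^2) / 2000)
  expect_true(all(abs(rowMeans(reps) - mu) < 3.5 * se))
  expect_lt(abs(mean(colSums(reps)) - lib), lib * 0.05)
  # dispersion -> 0 recovers Poisson variance
  set.seed(47)
  reps0 <- vapply(1:2000, function(i)
    noise_bulk_rnaseq(g, 1000, 0)[, 1], numeric(4))
  vm <- apply(reps0, 1, var) / rowMeans(reps0)
  expect_true(all(abs(vm - 1) < 0.2))
})

test_that("single-cell zeros match the logistic + NB composite", {
  mid <- 5; shape <- 1; phi <- 0.1; lib <- 1e4
  g <- matrix(mid, 50, 200)                    # at the midpoint: pi = 0.5
  rownames(g) <- paste0("g", 1:50)
  a <- 1 / 50                                  # equal abundances
  mu <- lib * a
  p_nb0 <- (1 + phi * mu)^(-1 / phi)
  expected <- 0.5 + 0.5 * p_nb0
  set.seed(48)
  counts <- noise_single_cell(g, phi, mid, shape, lib, sc_library_sd = 0)
  zf <- sum(counts == 0) / length(counts)
  n <- length(counts)
  expect_lt(abs(zf - expected), 3 * sqrt(expected * (1 - expected) / n))
  # dropout probability decreases with expression
  g_hi <- matrix(mid + 4, 50, 200, dimnames = dimnames(g))
  set.seed(49)
  counts_hi <- noise_single_cell(g_hi, phi, mid, shape, lib,
                                 sc_library_sd = 0)
  expect_lt(sum(counts_hi == 0) / length(counts_hi), zf)
})

test_that("the full expression pipeline is deterministic and consistent", {
  traj <- fx_small_traj()
  pws <- fx_small_pathways()
  params <- gene_expression_params(sample_freq = 4, n_cells = 8,
                                   single_cell = TRUE, seed = 77)
  r1 <- simulate_gene_expression(traj, pws, params)
  r2 <- simulate_gene_expression(traj, pws, params)
  expect_identical(r1$mean_matrix, r2$mean_matrix)
  expect_true(all(r1$noisy_matrix == r2$noisy_matrix))
  expect_identical(r1$sample_metadata, r2$sample_metadata)
  # sampling grid: 12 h every 4 h inclusive -> 4 times x 8 cells
  expect_identical(r1$sample_times, c(0, 4, 8, 12))
  expect_identical(ncol(r1$mean_matrix), 32L)
  # ground truth: the two type pathways partition every sampled cell
  expect_true(all(colSums(r1$activity_matrix[c("pwA", "pwB"), ]) == 1))
  # platform exclusivity
  expect_s4_class(r1$noisy_matrix, "dgCMatrix")
  bulk <- simulate_gene_expression(traj, pws,
    gene_expression_params(sample_freq = 6, n_cells = 8, seed = 77))
  expect_true(is.matrix(bulk$noisy_matrix))
  expect_identical(colnames(bulk$noisy_matrix), c("t0", "t6", "t12"))
})

test_that("an hours-0 trajectory yields a single sample at t = 0", {
  traj <- run_cell_model(model_params(8, 0, 0.01, seed = 2), cell_type("A"))
  pws <- fx_small_pathways()[3]                # M-transition pathway only
  res <- simulate_gene_expression(traj, pws,
    gene_expression_params(sample_freq = 4, n_cells = 5, seed = 1))
  expect_identical(res$sample_times, 0)
  expect_identical(ncol(res$mean_matrix), 1L)
})
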