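test_that("the bulk time-course scenario has the published shape", {
  sc <- fx_bulk()
  expect_identical(dim(sc$result$noisy_matrix), c(150L, 43L))
  expect_identical(sc$result$platform, "microarray")
  # contact-inhibition ground truth rises as the domain fills
  ci <- sc$result$activity_matrix["contact_inhibition", ]
  blocks <- tapply(ci, (seq_along(ci) - 1) %/% 6, mean)
  expect_true(all(diff(blocks) > -0.02))
  expect_gt(ci[43], ci[1] + 0.3)
})

test_that("scenario overrides are honored", {
  sc <- suppressWarnings(        # small override run under-fills n_cells
    scenario_bulk_microarray(overrides = list(hours = 24,
                                              initial_num = 40),
                             seed = 9))
  expect_identical(ncol(sc$result$noisy_matrix), 7L)   # 0..24 by 4
  expect_error(scenario_bulk_microarray(overrides = list(nope = 1)),
               "unknown override")
})

test_that("the two-type single-cell scenario separates the types", {
  sc <- fx_sc()
  act <- sc$result$activity_matrix
  expect_true(all(colSums(act[c("typeA", "typeB"), ]) == 1))
  expect_true(all(act[c("typeA", "typeB"), ] %in% c(0, 1)))

  # noise-free mean expression on type-A genes is strictly higher in
  # type-A cells (linear separability of the identity signal)
  meta <- sc$result$sample_metadata
  a_genes <- sc$pathways[[1]]$genes
  score <- colMeans(sc$result$mean_matrix[a_genes, ])
  expect_gt(min(score[meta$cell_type == "A"]),
            max(score[meta$cell_type == "B"]))

  # realized division intervals order the two types, A < B
  # founder intervals are kept: their nominal (negative) birth time makes
  # the first division a full-cycle estimate, and few non-founder type-B
  # cells complete a 36 h cycle inside the 48 h window
  iv_a <- division_intervals(sc$trajectory, "A", exclude_founders = FALSE)
  iv_b <- division_intervals(sc$trajectory, "B", exclude_founders = FALSE)
  expect_gt(length(iv_a), 20)
  expect_gt(length(iv_b), 5)
  expect_lt(mean(iv_a), mean(iv_b))

  # dropout introduces zeros beyond the NB-only process: the same noise
  # stream with dropout pushed to zero probability has fewer zeros
  params_nodrop <- sc$result$params
  params_nodrop$dropout_midpoint <- -1e9
  r_nodrop <- simulate_gene_expression(sc$trajectory, sc$pathways,
                                       params_nodrop)
  zf <- function(m) sum(m == 0) / length(m)
  expect_gt(zf(sc$result$noisy_matrix), zf(r_nodrop$noisy_matrix))
})

test_that("the confounded scenario differs only in gene-set overlap", {
  sc <- fixture("confound", scenario_growth_confounded(
    overrides = list(hours = 48, initial_num = 60, sample_freq = 12,
                     n_cells = 25), seed = 6))
  ga <- sc$pathways_disjoint[[1]]$genes
  gb <- sc$pathways_disjoint[[2]]$genes
  gd <- sc$pathways_disjoint[[3]]$genes
  gc_ <- sc$pathways_confounded[[3]]$genes
  expect_length(intersect(gd, c(ga, gb)), 0)
  expect_true(all(ga %in% gc_) && all(gb %in% gc_))
  # same trajectory, same sampled cells: only annotation differs
  expect_identical(sc$disjoint$sample_metadata, sc$confounded$sample_metadata)
  expect_identical(
    sc$disjoint$activity_matrix[c("typeA", "typeB"), ],
    sc$confounded$activity_matrix[c("typeA", "typeB"), ])
  # growth-rate ground truth is a real, non-binary signal
  gr <- sc$disjoint$activity_matrix["growth", ]
  expect_true(all(gr >= 0 & gr <= 1))
  expect_gt(sd(gr), 0.01)
})

test_that("scenarios are reproducible from (name, seed)", {
  s1 <- scenario_singlecell_twotype(overrides = list(hours = 12,
                                                     initial_num = 30),
                                    seed = 123)
  s2 <- scenario_singlecell_twotype(overrides = list(hours = 12,
                                                     initial_num = 30),
                                    seed = 123)
  expect_identical(s1$result$mean_matrix, s2$result$mean_matrix)
  expect_true(all(s1$result$noisy_matrix == s2$result$noisy_matrix))
  expect_identical(s1$trajectory$events, s2$trajectory$events)
})
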