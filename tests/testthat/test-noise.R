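test_that("down-sampling conserves the target total and never adds counts", {
  sim <- simulate_dataset(simulation_config(cells_per_sample = 30L,
                                            n_genes = 200L, seed = 9L))
  ds <- sim$dataset
  tgt <- min(Matrix::colSums(ds$counts))
  out <- downsample_library(ds, seed = 2L)
  expect_true(all(Matrix::colSums(out$counts) == tgt))
  expect_true(all(as.matrix(out$counts) <= as.matrix(ds$counts)))
  # a cell already at the target is returned unchanged
  at_target <- which(Matrix::colSums(ds$counts) == tgt)[1]
  expect_equal(out$counts[, at_target], ds$counts[, at_target])
})

test_that("down-sampling errors when the target exceeds a library", {
  m <- cbind(c(5, 5), c(1, 1))
  colnames(m) <- c("big", "small")
  ds <- toy_dataset(m, gene_names = c("a", "b"))
  expect_error(downsample_library(ds, target = 4L), "small")
})

test_that("down-sampled counts follow the hypergeometric mean", {
  # 10,000 independent cells each holding {A: 8, B: 2}, target 5:
  # E[A kept] = 5 * 8/10 = 4, Var = 5 * .8 * .2 * (10-5)/(10-1)
  n <- 10000L
  m <- matrix(rep(c(8, 2), n), nrow = 2)
  ds <- toy_dataset(m, gene_names = c("A", "B"))
  out <- downsample_library(ds, target = 5L, seed = 42L)
  a_kept <- as.numeric(out$counts[1, ])
  se <- sqrt(5 * 0.8 * 0.2 * 5 / 9) / sqrt(n)
  expect_lt(abs(mean(a_kept) - 4), 3 * se)
  expect_true(all(a_kept + as.numeric(out$counts[2, ]) == 5))
})

test_that("group balancing keeps the smaller group complete and is seeded", {
  cells <- tibble::tibble(
    cell = sprintf("c%03d", 1:42),
    age = rep(c("young", "old"), c(12, 30)),
    cell_type = "A"
  )
  sel <- balance_groups(cells, "A", seed = 1L)
  expect_length(sel, 24)
  expect_true(all(cells$cell[cells$age == "young"] %in% sel))
  expect_identical(sel, balance_groups(cells, "A", seed = 1L))
  expect_false(identical(sel, balance_groups(cells, "A", seed = 2L)))
  expect_error(balance_groups(cells, "Z"), "unknown cell type")
})

test_that("undersized groups are skipped with a reason", {
  cells <- tibble::tibble(
    cell = sprintf("c%03d", 1:59),
    age = rep(c("young", "old"), c(9, 50)),
    cell_type = "A"
  )
  sel <- balance_groups(cells, "A", min_cells_per_group = 10L)
  expect_length(sel, 0)
  expect_match(attr(sel, "reason"), "insufficient young")
})

test_that("noise distances match hand-computed centroid geometry", {
  # two identical cells: both distances zero
  expr <- cbind(c(1, 2), c(1, 2))
  colnames(expr) <- c("c1", "c2")
  rownames(expr) <- c("g1", "g2")
  cells <- tibble::tibble(cell = c("c1", "c2"), age = c("young", "young"))
  expect_equal(cell_noise(expr, cells)$noise_distance, c(0, 0))

  # cells (1,0) and (0,1): centroid (.5,.5), each at distance sqrt(.5)
  expr2 <- cbind(c(1, 0), c(0, 1))
  dimnames(expr2) <- list(c("g1", "g2"), c("c1", "c2"))
  d <- cell_noise(expr2, cells)$noise_distance
  expect_equal(d, rep(sqrt(0.5), 2), tolerance = 1e-12)

  # translation invariance: adding a constant to every gene of every cell
  d_shift <- cell_noise(expr2 + 3, cells)$noise_distance
  expect_equal(d_shift, d, tolerance = 1e-12)

  # a single-cell group is degenerate
  expect_error(cell_noise(expr2, tibble::tibble(cell = "c1", age = "young")),
               "at least 2")
})

test_that("noise ratios reproduce hand-computed estimators", {
  noise <- tibble::tibble(
    cell = sprintf("c%d", 1:4),
    sample = c("y1", "y1", "o1", "o1"),
    age = c("young", "young", "old", "old"),
    noise_distance = c(1, 1, 2, 2)
  )
  expect_equal(noise_ratios(noise)$log2_ratio_single_cell, 1)

  # young samples {1,1},{1,1}; old samples {4,4},{2,2}: sample-average
  # estimator log2((4+2)/2 / 1) = log2(3)
  noise2 <- tibble::tibble(
    cell = sprintf("c%d", 1:8),
    sample = rep(c("y1", "y2", "o1", "o2"), each = 2),
    age = rep(c("young", "old"), each = 4),
    noise_distance = c(1, 1, 1, 1, 4, 4, 2, 2)
  )
  r <- noise_ratios(noise2)
  expect_equal(r$log2_ratio_sample_average, log2(3), tolerance = 1e-12)

  # scale equivariance: distances times c leave both estimators unchanged
  scaled <- noise2
  scaled$noise_distance <- scaled$noise_distance * 7.3
  expect_equal(noise_ratios(scaled)[1:2], r[1:2], tolerance = 1e-12)

  # degenerate young group
  zero <- noise
  zero$noise_distance[1:2] <- 0
  expect_error(noise_ratios(zero), "degenerate")
})

test_that("the full noise analysis is deterministic and skips small groups", {
  sim <- simulate_dataset(simulation_config(
    cells_per_sample = 40L, n_genes = 300L,
    cell_types = c(A = 0.55, B = 0.42, C = 0.03), seed = 12L))
  ds <- normalize_counts(filter_cells(sim$dataset, qc_thresholds(0L, 1),
                                      verbose = FALSE))
  n1 <- transcriptional_noise(ds, seed = 5L)
  n2 <- transcriptional_noise(ds, seed = 5L)
  expect_identical(n1$summary, n2$summary)
  expect_identical(n1$cell_noise, n2$cell_noise)
  # the rare type C cannot reach 10 cells per group out of ~10 cells total
  expect_true("C" %in% n1$skipped$cell_type)
  expect_false("C" %in% n1$summary$cell_type)
  expect_match(n1$skipped$reason[n1$skipped$cell_type == "C"], "insufficient")
  expect_true(all(n1$cell_noise$noise_distance >= 0))
})

test_that("resampling averages independent passes", {
  sim <- simulate_dataset(simulation_config(cells_per_sample = 30L,
                                            n_genes = 200L, seed = 13L))
  ds <- normalize_counts(filter_cells(sim$dataset, qc_thresholds(0L, 1),
                                      verbose = FALSE))
  single <- lapply(1:2, function(r) {
    tidy(transcriptional_noise(ds, n_resamples = 1L,
                               seed = 5L + 7919L * (r - 1L)))
  })
  avg <- tidy(transcriptional_noise(ds, n_resamples = 2L, seed = 5L))
  manual <- (single[[1]]$log2_ratio_single_cell +
               single[[2]]$log2_ratio_single_cell) / 2
  expect_equal(avg$log2_ratio_single_cell, manual, tolerance = 1e-12)
})
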