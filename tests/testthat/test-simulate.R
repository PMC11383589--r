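test_that("planted loadings are normalized, anchored and reproducible", {
  W <- plant_loadings(10, 1, 0, seed = 1)
  expect_equal(sum(W), 1, tolerance = 1e-9)
  expect_true(all(W >= 0))

  W2 <- plant_loadings(1000, 5, 0.9, seed = 7)
  expect_equal(colSums(W2), rep(1, 5), tolerance = 1e-9,
               ignore_attr = TRUE)
  zero_frac <- colMeans(W2 == 0)
  expect_true(all(zero_frac >= 0.85))

  expect_identical(plant_loadings(1000, 5, 0.9, seed = 7), W2)

  # anchor guarantee: >= 5 genes at >= 3x the column mean, disjoint sets
  anchors <- attr(W2, "anchor_genes")
  for (j in 1:5) {
    expect_gte(length(anchors[[j]]), 5)
    expect_true(all(W2[anchors[[j]], j] >= 3 * mean(W2[, j])))
  }
  expect_equal(anyDuplicated(unlist(anchors)), 0)

  expect_error(plant_loadings(3, 5, 0, seed = 1))
  expect_error(plant_loadings(10, 2, 1, seed = 1))
  expect_error(plant_loadings(10, 2, -0.1, seed = 1))
})

test_that("counts are nonnegative integers with the configured library size", {
  co <- simulate_cohort(synthetic_config(
    n_cell_types = 4L, genes_per_type = 100L, programs_per_type = 3L,
    cells_per_sample_per_type = 100L, seed = 3
  ))
  libs <- unlist(lapply(co$counts, Matrix::colSums))
  expect_gte(length(libs), 10000)
  x <- unlist(lapply(co$counts, function(m) m@x))
  expect_true(all(x >= 0) && all(x == round(x)))
  expect_lt(abs(mean(libs) - 2000) / 2000, 0.1)
})

test_that("planted module correlation is realized on the latent usage scale", {
  spec <- list(list(id = 1L,
                    members = data.frame(cell_type = "CT1", program = 1:2),
                    rho = 0.8))
  cors <- vapply(1:20, function(s) {
    co <- simulate_cohort(synthetic_config(
      n_samples = 30L,
      group_sizes = c(HC = 7L, Inactive = 7L, Active = 8L,
                      TreatmentNaive = 8L),
      n_cell_types = 1L, genes_per_type = 40L, programs_per_type = 2L,
      cells_per_sample_per_type = 1L, module_spec = spec,
      activity_effect = 0, seed = s
    ))
    cor(co$truth$true_sample_usage[, 1], co$truth$true_sample_usage[, 2])
  }, numeric(1))
  expect_true(all(cors > 0.55 & cors < 0.95))
  expect_lt(abs(mean(cors) - 0.8), 0.05)
})

test_that("without an activity effect the VAS is unrelated to the module", {
  rhos <- vapply(1:20, function(s) {
    co <- simulate_cohort(synthetic_config(
      n_cell_types = 1L, genes_per_type = 40L, programs_per_type = 2L,
      cells_per_sample_per_type = 1L, activity_effect = 0, seed = s
    ))
    act <- names(co$truth$true_modules)[
      co$truth$true_modules == co$truth$activity_module]
    cor(co$truth$true_activity_score,
        rowMeans(co$truth$true_sample_usage[, act, drop = FALSE]),
        method = "spearman")
  }, numeric(1))
  expect_gte(mean(abs(rhos) < 0.5), 0.95)
})

test_that("a single near-noiseless program reproduces its planted loading", {
  co <- simulate_cohort(synthetic_config(
    n_cell_types = 1L, genes_per_type = 200L, programs_per_type = 1L,
    cells_per_sample_per_type = 40L, overdispersion = 0,
    libsize_mean = 20000L, seed = 11
  ))
  freq <- Matrix::rowSums(co$counts$CT1)
  freq <- freq / sum(freq)
  w <- co$truth$true_loadings$CT1[, 1]
  expect_gte(sum(freq * w) / sqrt(sum(freq^2) * sum(w^2)), 0.99)
})

test_that("identical config and seed give byte-identical cohorts", {
  cfg <- synthetic_config(n_cell_types = 1L, genes_per_type = 60L,
                          programs_per_type = 2L,
                          cells_per_sample_per_type = 5L, seed = 9)
  expect_identical(serialize(simulate_cohort(cfg), NULL),
                   serialize(simulate_cohort(cfg), NULL))
})

test_that("configuration invariants are enforced", {
  expect_error(synthetic_config(n_samples = 10), "sum")
  expect_error(synthetic_config(loading_sparsity = 1), "sparsity")
  expect_error(synthetic_config(overdispersion = -1))
  bad <- list(list(id = 1L,
                   members = data.frame(cell_type = "CT1", program = 1L),
                   rho = 0.5),
              list(id = 2L,
                   members = data.frame(cell_type = "CT1", program = 1L),
                   rho = 0.5))
  expect_error(synthetic_config(module_spec = bad), "at most one module")
})
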