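test_that("panels have the declared shape, truth table and determinism", {
  p <- simulate_panel(models = "P", n_features_per_model = 10,
                      n_samples = 500, seed = 3)
  expect_equal(dim(p$matrix), c(10L, 500L))
  expect_true(all(p$matrix >= 0 & p$matrix == floor(p$matrix)))
  expect_equal(p$truth, rep("P", 10))
  p2 <- simulate_panel(models = "P", n_features_per_model = 10,
                       n_samples = 500, seed = 3)
  expect_identical(p$matrix, p2$matrix)
  p3 <- simulate_panel(models = "P", n_features_per_model = 10,
                       n_samples = 500, seed = 4)
  expect_false(identical(p$matrix, p3$matrix))

  full <- simulate_panel(n_features_per_model = 2, n_samples = 60, seed = 1)
  expect_equal(dim(full$matrix), c(22L, 60L))
  expect_equal(unique(full$truth), model_names())
  expect_error(simulate_panel(n_samples = 10),
               class = "m3s_error_invalid_params")
})

test_that("outlier injection replaces the right number of rows", {
  p <- simulate_panel(models = "P", n_features_per_model = 100,
                      n_samples = 60, seed = 5)
  p0 <- inject_outliers(p, "MG", fraction = 0, seed = 1)
  expect_identical(p0$matrix, p$matrix)
  expect_equal(sum(p0$outlier_mask), 0L)

  p5 <- inject_outliers(p, "MG", fraction = 0.05, seed = 1)
  expect_equal(sum(p5$outlier_mask), 5L)
  expect_equal(sum(p5$truth == "MG"), 5L)
  changed <- rowSums(p5$matrix != p$matrix) > 0
  expect_equal(unname(which(changed)), which(p5$outlier_mask))

  expect_error(inject_outliers(p, "MG", fraction = 0.5, seed = 1),
               class = "m3s_error_invalid_params")
  expect_error(inject_outliers(p, "P", fraction = 0.05, seed = 1),
               class = "m3s_error_invalid_params")
})

test_that("platform generators reproduce the stated signatures", {
  fish <- simulate_platform("fish", n_genes = 20, n_cells = 347, seed = 2)
  expect_lt(mean(fish == 0), 0.05)

  sat <- simulate_platform("saturated", n_genes = 50, n_cells = 200, seed = 2)
  floor_val <- attr(sat, "config")$floor
  expect_gte(mean(apply(sat, 1, min) == floor_val), 0.99)

  umi <- simulate_platform("umi", n_genes = 60, n_cells = 100, seed = 2)
  zf <- colMeans(umi == 0)
  expect_gt(sd(zf) / mean(zf), 0.1)
  expect_true(all(umi == floor(umi)))
})
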