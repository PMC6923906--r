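test_that("peak assignment follows the posterior and zero/censor rules", {
  x <- rnorm(20)
  expect_equal(assign_peaks(x, model_fit("G", list(mu = 0, sigma = 1))),
               rep(1L, 20))
  f <- model_fit("ZIMG", list(weights = 1, mus = 3, sigmas = 1, pi0 = 1))
  expect_equal(assign_peaks(rep(0, 10), f), rep(0L, 10))
  f <- model_fit("MG", list(weights = c(0.5, 0.5), mus = c(0, 10),
                            sigmas = c(1, 1)))
  expect_equal(assign_peaks(c(0.1, 9.8), f), c(1L, 2L))
  # censored values get label 0 under LTMG; peak index ascends with mean
  f <- model_fit("LTMG", list(weights = c(0.3, 0.4, 0.3), mus = c(0, 3, 7),
                              sigmas = c(1, 0.5, 0.5), zcut = 1))
  expect_equal(assign_peaks(c(1, 3.1, 7.2, 1, 2.9), f),
               c(0L, 2L, 3L, 0L, 2L))
  # ZIP zeros go to the inflation mass when it owns the posterior
  f <- model_fit("ZIP", list(lambda = 8, pi0 = 0.4))
  expect_equal(assign_peaks(c(0, 3), f), c(0L, 1L))
})

test_that("hypergeometric upper tail matches enumeration and symmetry", {
  expect_equal(hypergeom_enrichment(4, 4, 5, 10), 5 / 210)
  expect_equal(hypergeom_enrichment(3, 6, 6, 6), 1)  # peak = population
  expect_equal(hypergeom_enrichment(0, 3, 3, 10), 1)
  expect_equal(hypergeom_enrichment(2, 3, 5, 11),
               hypergeom_enrichment(2, 5, 3, 11))
  expect_error(hypergeom_enrichment(5, 4, 5, 10),
               class = "m3s_error_invalid_data")
  # spot-check the exhaustive oracle
  expect_equal(hypergeom_enrichment(2, 4, 5, 10), enum_hyper(2, 4, 5, 10))
  expect_equal(hypergeom_enrichment(3, 5, 6, 12), enum_hyper(3, 5, 6, 12))
})

test_that("planted two-class design is called differentially expressed", {
  n <- 500
  lab_true <- withr::with_seed(21, sample(rep(1:2, each = n / 2)))
  x <- ifelse(lab_true == 1, rnorm(n, 1, 0.5), rnorm(n, 6, 0.5))
  m <- matrix(x, 1, dimnames = list("g1", paste0("s", 1:n)))
  res <- m3s(m, normalization = "none", seed = 4)
  classes <- ifelse(lab_true == 1, "A", "B")
  de <- m3s_test(m, classes, res)
  hit <- de[de$peak == 2 & de$class_name == "B", ]
  expect_equal(nrow(hit), 1L)
  expect_lt(hit$fdr, 0.05)
  expect_true(hit$de)

  # single class: every test is against the whole population
  de1 <- m3s_test(m, rep("all", n), res)
  expect_true(all(de1$p_value == 1))

  expect_error(m3s_test(m, classes[-1], res),
               class = "m3s_error_label_mismatch")
})

test_that("top_peak_only restricts testing to the highest peak", {
  x <- model_sample("MG", list(weights = c(0.5, 0.5), mus = c(1, 6),
                               sigmas = c(0.5, 0.5)), 200, seed = 12)
  m <- matrix(x, 1, dimnames = list("g1", paste0("s", 1:200)))
  res <- m3s(m, normalization = "none", seed = 4)
  classes <- rep(c("A", "B"), 100)
  de <- m3s_test(m, classes, res, top_peak_only = TRUE)
  expect_true(all(de$peak == max(de$peak)))
})
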