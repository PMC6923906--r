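test_that("KS statistic at plug-in quantiles is minimal", {
  n <- 100
  fit <- model_fit("G", list(mu = 0, sigma = 1))
  x <- qnorm((seq_len(n) - 0.5) / n)
  expect_lte(ks_gof(x, fit)$ks_stat, 0.5 / n + 1e-9)
})

test_that("KS statistic equals a dense-grid oracle", {
  fit <- model_fit("G", list(mu = 0, sigma = 1))
  x <- c(0, 1)
  d <- ks_gof(x, fit)$ks_stat
  expect_equal(d, grid_ks(x, function(q) pnorm(q), -6, 6), tolerance = 1e-4)
  # atom-aware case: censored model against data with ties at the floor
  p <- list(mu = 2, sigma = 1, zcut = 1.5)
  x <- model_sample("LTG", p, 400, seed = 5)
  fit <- model_fit("LTG", p)
  d <- ks_gof(x, fit)$ks_stat
  oracle <- grid_ks(x, function(q) model_cdf("LTG", p, q), 1, 7)
  expect_equal(d, oracle, tolerance = 1e-3)
})

test_that("discrete-support KS matches direct evaluation over the grid", {
  x <- withr::with_seed(2, rpois(200, 4))
  fit <- fit_model(x, "P")
  grid <- (min(x) - 1):max(x)
  d_manual <- max(abs(ecdf(x)(grid) - ppois(grid, fit$params$lambda)))
  expect_equal(ks_gof(x, fit)$ks_stat, d_manual)
})

test_that("BH adjustment equals the hand-computed step-up", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(fdr_adjust(0.37), 0.37)
  expect_equal(fdr_adjust(c(0.1, NA, 0.2)), c(0.2, NA, 0.2))
  expect_error(fdr_adjust(c(0.5, 1.2)), class = "m3s_error_invalid_data")
  # agrees with the reference implementation on random input
  p <- withr::with_seed(8, runif(50))
  expect_equal(fdr_adjust(p), p.adjust(p, "BH"))
})

test_that("candidate model lists depend on data type and zeros", {
  counts <- assess_characteristics(matrix(c(0L, 2L, 5L, 7L), 2))
  expect_setequal(candidate_models(counts, "log_cpm1p"), model_names())
  logreal <- assess_characteristics(matrix(c(0, 1.3, 2.7, 3.1), 2))
  expect_setequal(candidate_models(logreal, "identity"),
                  c("G", "ZIG", "LTG", "MG", "ZIMG", "LTMG"))
  posreal <- assess_characteristics(matrix(c(0.4, 1.3, 2.7, 3.1), 2))
  expect_setequal(candidate_models(posreal, "identity"),
                  c("G", "LTG", "MG", "LTMG"))
  # ordered by complexity rank
  cm <- candidate_models(counts, "log_cpm1p")
  expect_true(all(diff(model_rank(cm)) >= 0))
})

test_that("parsimony rule picks the simplest passing model", {
  mk <- function(model, fdr, p, params) {
    f <- model_fit(model, params)
    f$ks_fdr <- fdr; f$ks_pvalue <- p
    f
  }
  fits <- list(
    P = mk("P", 0.5, 0.2, list(lambda = 2)),
    MG = mk("MG", 0.9, 0.9, list(weights = 1, mus = 0, sigmas = 1)))
  expect_equal(select_best(fits)$best_model, "P")
  expect_true(select_best(fits)$adequate)

  fits <- list(LTMG = mk("LTMG", 0.4, 0.4,
                         list(weights = 1, mus = 2, sigmas = 1, zcut = 0)))
  expect_equal(select_best(fits)$best_model, "LTMG")

  fits <- list(
    P = mk("P", 0.01, 0.001, list(lambda = 2)),
    G = mk("G", 0.05, 0.02, list(mu = 0, sigma = 1)))
  s <- select_best(fits)
  expect_false(s$adequate)
  expect_equal(s$best_model, "G")   # provisional argmax-p

  # rank tie: preference list wins, otherwise larger p
  fits <- list(
    ZIMG = mk("ZIMG", 0.5, 0.3, list(weights = 1, mus = 2, sigmas = 1,
                                     pi0 = 0.2)),
    LTMG = mk("LTMG", 0.5, 0.6, list(weights = 1, mus = 2, sigmas = 1,
                                     zcut = 0)))
  expect_equal(select_best(fits)$best_model, "LTMG")
  expect_equal(select_best(fits, prefer = "ZIMG")$best_model, "ZIMG")
  expect_error(select_best(list()), class = "m3s_error_invalid_data")
})

test_that("Mann-Whitney peak comparison handles ties and extremes", {
  expect_equal(peak_parsimony_test(rep(2, 10), rep(2, 10)), 0.5)
  expect_lt(peak_parsimony_test(rep(1, 5), rep(3, 5)), 0.01)
  expect_gte(peak_parsimony_test(2, 2), 0.5)
  # consistency with the reference implementation on untied data
  a <- c(1, 2, 2, 3, 1, 2); b <- c(2, 3, 3, 4, 3, 4)
  ref <- suppressWarnings(stats::wilcox.test(a, b, alternative = "less",
                                             exact = FALSE,
                                             correct = TRUE)$p.value)
  expect_equal(peak_parsimony_test(a, b), ref, tolerance = 1e-8)
})

test_that("m3s recovers simple planted structure", {
  m <- withr::with_seed(5, matrix(rpois(50 * 300, 5), 50, 300))
  res <- m3s(m, seed = 2)
  expect_gte(mean(res$summary$best_model == "P"), 0.8)

  x <- model_sample("MG", list(weights = c(0.5, 0.5), mus = c(1, 6),
                               sigmas = c(0.5, 0.5)), 500, seed = 31)
  res <- m3s(matrix(x, 1), normalization = "none", seed = 3)
  expect_true(res$summary$best_model %in% c("MG", "LTMG"))
  expect_equal(res$summary$n_peaks, 2L)

  expect_error(m3s(matrix(numeric(0), 0, 10)),
               class = "m3s_error_invalid_data")
  expect_error(m3s(matrix(1:9, 1)), class = "m3s_error_too_few_samples")
})

test_that("m3s is deterministic given a seed", {
  panel <- simulate_panel(models = c("G", "MG"), n_features_per_model = 3,
                          n_samples = 120, seed = 9)
  r1 <- m3s(panel$matrix, normalization = "none", seed = 77)
  r2 <- m3s(panel$matrix, normalization = "none", seed = 77)
  expect_identical(r1, r2)
})
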