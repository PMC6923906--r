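test_that("model registry encodes the complexity ordering", {
  expect_length(model_names(), 11L)
  r <- function(m) model_rank(m)
  expect_true(r("P") < r("NB"))
  expect_equal(r("NB"), r("G"))
  expect_true(r("G") < r("ZIP"))
  expect_equal(r("ZINB"), r("ZIG"))
  expect_equal(r("ZIG"), r("LTG"))
  expect_true(r("LTG") < r("BP"))
  expect_true(r("BP") < r("MG"))
  expect_true(r("MG") < r("ZIMG"))
  expect_equal(r("ZIMG"), r("LTMG"))
  expect_error(model_rank("XYZ"), class = "m3s_error_unknown_model")
})

test_that("parameter validation rejects malformed parameter sets", {
  expect_error(validate_params("P", list(lambda = -1)),
               class = "m3s_error_invalid_params")
  expect_error(validate_params("ZIP", list(lambda = 2, pi0 = 1.2)),
               class = "m3s_error_invalid_params")
  expect_error(validate_params("MG", list(weights = c(0.5, 0.6),
                                          mus = c(0, 1), sigmas = c(1, 1))),
               class = "m3s_error_invalid_params")
  expect_error(validate_params("MG", list(weights = 1, mus = c(0, 1),
                                          sigmas = 1)),
               class = "m3s_error_invalid_params")
  expect_silent(validate_params("LTMG", ref_params$LTMG))
})

test_that("closed-form fits match their textbook estimators", {
  x <- rep(2, 10)
  f <- fit_model(x, "P")
  expect_equal(f$params$lambda, 2)
  expect_equal(f$loglik, 10 * dpois(2, 2, log = TRUE))

  x <- model_sample("G", list(mu = 5, sigma = 1), 500, seed = 42)
  f <- fit_model(x, "G")
  expect_equal(f$params$mu, mean(x))                      # exact MLE
  expect_equal(f$params$sigma, sqrt(mean((x - mean(x))^2)))
  expect_lt(abs(f$params$mu - 5), 3 / sqrt(500))
})

test_that("planted two-component mixture is recovered, k-means as oracle", {
  x <- model_sample("MG", ref_params$MG, 500, seed = 7)
  f <- fit_model(x, "MG", max_components = 5)
  expect_equal(f$n_components, 2L)
  expect_lt(max(abs(sort(f$params$mus) - c(0, 6))), 0.3)
  km <- withr::with_seed(1, stats::kmeans(x, centers = 2, nstart = 5))
  expect_lt(max(abs(sort(f$params$mus) - sort(as.numeric(km$centers)))), 0.3)
})

test_that("fitters enforce model support", {
  expect_error(fit_model(c(rnorm(20)), "P"),
               class = "m3s_error_unsupported_data")
  expect_error(fit_model(seq(0.5, 5, by = 0.5), "NB"),
               class = "m3s_error_unsupported_data")
  expect_error(fit_model(1:20, "ZIP"),
               class = "m3s_error_unsupported_data") # no zeros
  expect_error(fit_model(1:5, "G"), class = "m3s_error_too_few_samples")
})

test_that("model CDFs are normalized, monotone and hit known values", {
  expect_equal(model_cdf("G", list(mu = 0, sigma = 1), 0), 0.5)
  expect_equal(model_cdf("LTG", list(mu = 0, sigma = 1, zcut = 0), 1e6), 1)
  for (m in model_names()) {
    p <- ref_params[[m]]
    q <- seq(-5, 120, length.out = 80)
    cdf <- model_cdf(m, p, q)
    expect_true(all(diff(cdf) >= -1e-12), info = m)
    expect_true(all(cdf >= 0 & cdf <= 1), info = m)
    expect_equal(model_cdf(m, p, 1e7), 1, tolerance = 1e-6, info = m)
  }
  # censoring semantics: no mass below zcut, full base mass at zcut
  p <- ref_params$LTG
  expect_equal(model_cdf("LTG", p, p$zcut - 1e-9), 0)
  expect_equal(model_cdf("LTG", p, p$zcut),
               pnorm(p$zcut, p$mu, p$sigma))
})

test_that("BP quadrature CDF matches a Monte-Carlo oracle", {
  p <- list(alpha = 2, beta = 4, scale = 20)
  x <- model_sample("BP", p, 1e6, seed = 123)
  for (q in c(1, 3, 5, 8, 12)) {
    mc <- mean(x <= q)
    se <- sqrt(mc * (1 - mc) / 1e6)
    expect_lt(abs(model_cdf("BP", p, q) - mc), 3 * se + 1e-9)
  }
})

test_that("samplers honour their construction", {
  x <- model_sample("P", list(lambda = 3), 1e5, seed = 1)
  expect_lt(abs(mean(x) - 3), 3 * sqrt(3 / 1e5))
  expect_true(all(model_sample("ZIP", list(lambda = 5, pi0 = 1), 100,
                               seed = 2) == 0))
  # one-component mixture is indistinguishable from the plain Gaussian
  x <- model_sample("MG", list(weights = 1, mus = 2, sigmas = 1), 1000,
                    seed = 3)
  expect_gt(suppressWarnings(
    stats::ks.test(x, pnorm, mean = 2, sd = 1)$p.value), 0.01)
  # identical seeds give identical draws; censor mode floors at zcut
  expect_identical(model_sample("NB", ref_params$NB, 50, seed = 9),
                   model_sample("NB", ref_params$NB, 50, seed = 9))
  x <- model_sample("LTG", ref_params$LTG, 500, seed = 4)
  expect_gte(min(x), ref_params$LTG$zcut)
  expect_gt(mean(x == ref_params$LTG$zcut), 0.05)
  x <- model_sample("LTG", ref_params$LTG, 500, seed = 4, lt_mode = "reject")
  expect_equal(sum(x == ref_params$LTG$zcut), 0)
})

test_that("peak counts exclude the zero/censored mass", {
  expect_equal(peak_count(model_fit("G", list(mu = 0, sigma = 1))), 1L)
  expect_equal(peak_count(model_fit("ZIMG", list(
    weights = c(0.3, 0.3, 0.4), mus = 1:3, sigmas = rep(0.5, 3),
    pi0 = 0.4))), 3L)
  expect_equal(peak_count(model_fit("LTMG", list(
    weights = c(0.5, 0.5), mus = c(1, 4), sigmas = c(1, 1), zcut = 0))), 2L)
  expect_equal(peak_count(model_fit("ZIP", list(lambda = 3, pi0 = 0.5))), 1L)
})

test_that("zero-inflated fits dominate their base model on zero-laden data", {
  for (seeds in 1:5) {
    x <- model_sample("ZIP", list(lambda = 6, pi0 = 0.3), 200, seed = seeds)
    lp <- fit_model(x, "P")$loglik
    lzip <- fit_model(x, "ZIP")$loglik
    expect_gte(lzip, lp - 1e-6)
  }
})

test_that("mixture log-likelihood is nondecreasing in K", {
  x <- model_sample("MG", ref_params$MG, 300, seed = 11)
  lls <- vapply(1:4, function(k) {
    inits <- m3select:::kmeans_inits(x, k, rep(FALSE, 300), -Inf, seed = 5)
    max(vapply(inits, function(i)
      m3select:::em_mixture(x, k, init = i)$loglik, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(lls) >= -1e-4))
})

test_that("fit serialization is key=value;-joined", {
  f <- model_fit("ZIP", list(lambda = 2.5, pi0 = 0.25))
  expect_equal(format_params(f$params), "lambda=2.5;pi0=0.25")
})
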