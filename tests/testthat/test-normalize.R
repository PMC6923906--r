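test_that("characteristic screens evaluate the four predicates", {
  m <- matrix(rpois(100, 2), 10)           # integer counts, many zeros
  ch <- withr::with_seed(1, assess_characteristics(matrix(rpois(100, 1), 10)))
  expect_true(ch$nonnegative)
  expect_true(ch$high_zero_proportion)
  expect_true(ch$discretized)
  expect_false(ch$has_negative_infinite)
  expect_equal(ch$zero_fraction, mean(withr::with_seed(1, rpois(100, 1)) == 0))

  ch <- assess_characteristics(matrix(c(-Inf, 1.5, 2.2, 3), 2))
  expect_true(ch$has_negative_infinite)
  expect_false(ch$discretized)

  ch <- assess_characteristics(matrix(runif(50) + 0.1, 5))
  expect_false(ch$high_zero_proportion)
  expect_false(ch$discretized)

  expect_error(assess_characteristics(matrix(c(1, NA), 1)),
               class = "m3s_error_invalid_data")
})

test_that("normalization decision tree", {
  mk <- function(m) assess_characteristics(m)
  expect_equal(select_normalization(mk(matrix(c(0L, 3L, 4L, 9L), 2))),
               "log_cpm1p")
  expect_equal(select_normalization(mk(matrix(1:8, 2))), "log_cpm")
  expect_equal(select_normalization(mk(matrix(c(0, 1.5, 2.7, 3.1), 2))),
               "log1p")
  expect_equal(select_normalization(mk(matrix(c(0.2, 1.5, 2.7, 3.1), 2))),
               "log")
  expect_equal(select_normalization(mk(matrix(c(-1.5, 2.5), 1))), "identity")
  expect_equal(select_normalization(mk(matrix(c(-Inf, 2.5), 1))), "identity")
})

test_that("transforms follow their formulas", {
  m <- matrix(c(1, 1, 2), 3, 1)
  expect_equal(as.numeric(apply_normalization(m, "cpm")),
               c(250000, 250000, 500000))
  m2 <- matrix(c(0, 9), 2, 1)
  expect_equal(as.numeric(apply_normalization(m2, "log_cpm1p")),
               c(log(1), log(9e6 / 9 + 1)))
  expect_equal(as.numeric(apply_normalization(m, "identity")),
               as.numeric(m))
  expect_error(apply_normalization(matrix(c(0, 1), 1), "log"),
               class = "m3s_error_invalid_transform")
})

test_that("CPM conserves column totals and flags zero libraries", {
  m <- withr::with_seed(3, matrix(rpois(300, 4), 30))
  cm <- apply_normalization(m, "cpm")
  expect_true(all(abs(colSums(cm) - 1e6) < 1e-6))
  m[, 4] <- 0
  cm <- apply_normalization(m, "cpm")
  expect_equal(attr(cm, "zero_library"), 4L)
  expect_true(all(cm[, 4] == 0))
})

test_that("auto-selected transform never fails and is monotone", {
  gens <- list(function() matrix(rpois(200, 3), 20),
               function() matrix(abs(rnorm(200)) + 0.01, 20),
               function() matrix(rnorm(200), 20),
               function() matrix(c(0, runif(199)), 20))
  for (i in seq_along(gens)) {
    m <- withr::with_seed(i, gens[[i]]())
    ch <- assess_characteristics(m)
    tr <- select_normalization(ch)
    expect_no_error(out <- apply_normalization(m, tr))
    # strictly increasing on the entries of any one column
    o1 <- order(m[, 1]); v <- out[, 1][o1]
    expect_true(all(diff(v) >= 0))
  }
})
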