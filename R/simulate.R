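#' Default benchmark parameter ranges
#'
#' Reads the version-controlled config shipped with the package
#' (`inst/extdata/benchmark_params.json`): per-model sampling ranges chosen
#' so that adjacent model families are distinguishable at 500 samples.
#'
#' @return Named list of per-model range lists.
#' @export
benchmark_param_ranges <- function() {
  path <- system.file("extdata", "benchmark_params.json",
                      package = "m3select")
  if (path == "") path <- file.path("inst", "extdata", "benchmark_params.json")
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cfg$comment <- NULL
  cfg
}

runif1 <- function(r) stats::runif(1, r[1], r[2])

# Draw one concrete parameter set for `model` from its ranges. Must be
# called inside a withr::with_seed block.
draw_params <- function(model, ranges) {
  r <- ranges[[model]]
  mix_chain <- function(k, mu1, gap_r, sig_r, min_w) {
    mus <- mu1 + c(0, cumsum(stats::runif(k - 1, gap_r[1], gap_r[2])))
    sigmas <- stats::runif(k, sig_r[1], sig_r[2])
    w <- stats::runif(k, min_w, 1)
    list(weights = w / sum(w), mus = mus, sigmas = sigmas)
  }
  switch(model,
    P = list(lambda = runif1(r$lambda)),
    NB = { size <- runif1(r$size); mu <- runif1(r$mu)
           list(size = size, prob = size / (size + mu)) },
    G = list(mu = runif1(r$mu), sigma = runif1(r$sigma)),
    ZIP = list(lambda = runif1(r$lambda), pi0 = runif1(r$pi0)),
    ZINB = { size <- runif1(r$size); mu <- runif1(r$mu)
             list(size = size, prob = size / (size + mu),
                  pi0 = runif1(r$pi0)) },
    ZIG = list(mu = runif1(r$mu), sigma = runif1(r$sigma),
               pi0 = runif1(r$pi0)),
    LTG = { mu <- runif1(r$mu); sigma <- runif1(r$sigma)
            list(mu = mu, sigma = sigma,
                 zcut = mu - runif1(r$zcut_offset) * sigma) },
    BP = list(alpha = runif1(r$alpha), beta = runif1(r$beta),
              scale = runif1(r$scale)),
    MG = {
      k <- sample(r$k[1]:r$k[2], 1)
      mix_chain(k, runif1(r$mu1), r$gap, r$sigma, r$min_weight)
    },
    ZIMG = {
      k <- sample(r$k[1]:r$k[2], 1)
      c(mix_chain(k, runif1(r$mu1), r$gap, r$sigma, r$min_weight),
        list(pi0 = runif1(r$pi0)))
    },
    LTMG = {
      k_up <- sample((r$k[1] - 1):(r$k[2] - 1), 1)
      up <- mix_chain(k_up, runif1(r$mu2), r$gap, r$sigma, 0.2)
      w1 <- runif1(r$w1)
      list(weights = c(w1, (1 - w1) * up$weights),
           mus = c(runif1(r$mu1), up$mus),
           sigmas = c(runif1(r$sigma1), up$sigmas),
           zcut = r$zcut)
    },
    stop_m3s("unknown_model", "no ranges for model ", model)
  )
}

#' Simulate a benchmark feature panel
#'
#' For each requested model, draws `n_features_per_model` features of
#' `n_samples` i.i.d. observations each, with generating parameters sampled
#' from the configured ranges. Mirrors the validation design of fitting
#' candidate distributions to homogeneous feature blocks.
#'
#' @param models Character vector of generating models.
#' @param n_features_per_model Features per model (benchmark default 100).
#' @param n_samples Samples per feature (>= 50; benchmark default 500).
#' @param seed Integer seed; the full panel is reproducible from it.
#' @param param_ranges Ranges as from [benchmark_param_ranges()].
#' @return List with `matrix` (features x samples), `truth` (generating
#'   model per row) and `params` (list of generating parameter sets).
#' @export
simulate_panel <- function(models = model_names(), n_features_per_model = 100L,
                           n_samples = 500L, seed = 1L,
                           param_ranges = benchmark_param_ranges()) {
  if (n_samples < 50L)
    stop_m3s("invalid_params", "n_samples must be >= 50")
  missing_r <- setdiff(models, names(param_ranges))
  if (length(missing_r) > 0)
    stop_m3s("invalid_params", "no parameter ranges for: ",
             paste(missing_r, collapse = ", "))
  rows <- list(); truth <- character(0); pars <- list()
  ridx <- 0L
  for (mod in models) {
    for (j in seq_len(n_features_per_model)) {
      ridx <- ridx + 1L
      fseed <- (seed + 104729L * ridx) %% 2147483647L
      p <- withr::with_seed(fseed, draw_params(mod, param_ranges))
      rows[[ridx]] <- model_sample(mod, p, n_samples,
                                   seed = (fseed + 1L) %% 2147483647L)
      truth[ridx] <- mod
      pars[[ridx]] <- p
    }
  }
  mat <- do.call(rbind, rows)
  rownames(mat) <- sprintf("f%04d_%s", seq_len(nrow(mat)), truth)
  colnames(mat) <- sprintf("s%03d", seq_len(n_samples))
  list(matrix = mat, truth = truth, params = pars)
}

#' Replace a random minority of panel rows with draws from another model
#'
#' @param panel Output of [simulate_panel()] (assumed homogeneous).
#' @param outlier_model Generating model for the planted outliers; must
#'   differ from the panel's majority model.
#' @param fraction Fraction of rows to replace, in \[0, 0.5).
#' @param seed Integer seed.
#' @param param_ranges Ranges as from [benchmark_param_ranges()].
#' @return The panel with `matrix`, `truth` updated and `outlier_mask`
#'   (logical per row) added.
#' @export
inject_outliers <- function(panel, outlier_model, fraction, seed,
                            param_ranges = benchmark_param_ranges()) {
  if (fraction >= 0.5)
    stop_m3s("invalid_params", "outliers must stay a minority (fraction < 0.5)")
  majority <- names(which.max(table(panel$truth)))
  if (outlier_model == majority)
    stop_m3s("invalid_params",
             "outlier model must differ from the majority model")
  n <- nrow(panel$matrix)
  n_out <- ceiling(fraction * n)
  mask <- rep(FALSE, n)
  if (n_out > 0) {
    idx <- withr::with_seed(seed, sample.int(n, n_out))
    mask[idx] <- TRUE
    for (i in idx) {
      fseed <- (seed + 15485863L + 104729L * i) %% 2147483647L
      p <- withr::with_seed(fseed, draw_params(outlier_model, param_ranges))
      panel$matrix[i, ] <- model_sample(outlier_model, p,
                                        ncol(panel$matrix),
                                        seed = (fseed + 1L) %% 2147483647L)
      panel$truth[i] <- outlier_model
      panel$params[[i]] <- p
    }
  }
  panel$outlier_mask <- mask
  panel
}

#' Simulate a platform-shaped expression matrix
#'
#' Emulates the distributional signatures of three platform families:
#' `"saturated"` (SMART-seq-like log-scale values left-censored at a global
#' detection floor, the LTMG regime), `"umi"` (10x-like counts with
#' cell-varying dropout rates, the ZIMG regime) and `"fish"` (multi-modal
#' molecule counts with very few zeros, the MG regime).
#'
#' @param kind One of `"saturated"`, `"umi"`, `"fish"`.
#' @param n_genes,n_cells Matrix dimensions.
#' @param seed Integer seed.
#' @return Gene x cell numeric matrix (attribute `config` records the
#'   generating parameters).
#' @export
simulate_platform <- function(kind = c("saturated", "umi", "fish"),
                              n_genes, n_cells, seed = 1L) {
  kind <- match.arg(kind)
  if (n_genes < 1L || n_cells < 1L)
    stop_m3s("invalid_params", "n_genes and n_cells must be >= 1")
  ranges <- benchmark_param_ranges()
  cfg <- list(kind = kind)
  mat <- withr::with_seed(seed, switch(kind,
    saturated = {
      cfg$floor <- 1
      t(vapply(seq_len(n_genes), function(i) {
        p <- draw_params("LTMG", ranges)
        k <- sample.int(length(p$weights), n_cells, replace = TRUE,
                        prob = p$weights)
        x <- stats::rnorm(n_cells, p$mus[k], p$sigmas[k])
        pmax(x, 1)
      }, numeric(n_cells)))
    },
    umi = {
      # cell-specific dropout rates on top of a mixture of expression states
      drop <- stats::rbeta(n_cells, 4, 6)   # mean 0.4, sd ~0.15
      cfg$dropout <- drop
      t(vapply(seq_len(n_genes), function(i) {
        p <- draw_params("ZIMG", ranges)
        k <- sample.int(length(p$weights), n_cells, replace = TRUE,
                        prob = p$weights)
        x <- round(exp(stats::rnorm(n_cells, p$mus[k], p$sigmas[k]))) # counts
        x[stats::runif(n_cells) < drop] <- 0
        x
      }, numeric(n_cells)))
    },
    fish = {
      t(vapply(seq_len(n_genes), function(i) {
        p <- draw_params("MG", ranges)
        p$mus <- p$mus + 2  # keep molecule counts away from zero
        k <- sample.int(length(p$weights), n_cells, replace = TRUE,
                        prob = p$weights)
        pmax(round(exp(stats::rnorm(n_cells, p$mus[k], p$sigmas[k] / 2))), 1)
      }, numeric(n_cells)))
    }
  ))
  dimnames(mat) <- list(sprintf("g%04d", seq_len(n_genes)),
                        sprintf("c%04d", seq_len(n_cells)))
  attr(mat, "config") <- cfg
  mat
}
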