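#' Model-identification benchmark
#'
#' Reproduces the simulation validation: for each generating model, a
#' homogeneous panel of features is simulated, the full selection pipeline
#' is run, and a feature is scored correct when the selected model equals
#' the generating one. Count-model panels go through the automatic
#' normalization (count candidates fit the raw counts); continuous-model
#' panels are already on the model scale and use the identity transform.
#'
#' @param n_features_per_model Features per generating model (default 30;
#'   the full-scale design uses 100).
#' @param n_samples Samples per feature (default 500).
#' @param models Generating models (default all 11).
#' @param seed Integer seed.
#' @param fdr_threshold KS FDR threshold for the parsimony rule.
#' @param max_components Mixture component cap.
#' @param verbose Log progress.
#' @return List of class `m3s_benchmark`: `overall_accuracy`,
#'   `per_model` (data.frame model/n/accuracy), `selected` (per-feature
#'   selected model), `truth`.
#' @export
m3s_benchmark <- function(n_features_per_model = 30L, n_samples = 500L,
                          models = model_names(), seed = 1L,
                          fdr_threshold = 0.1, max_components = 5L,
                          verbose = TRUE) {
  truth_all <- character(0); sel_all <- character(0)
  per <- data.frame(model = models, n = NA_integer_, accuracy = NA_real_)
  for (j in seq_along(models)) {
    mod <- models[j]
    panel <- simulate_panel(models = mod,
                            n_features_per_model = n_features_per_model,
                            n_samples = n_samples,
                            seed = (seed + 7L * j) %% 2147483647L)
    norm <- if (is_count_model(mod)) "auto" else "none"
    res <- m3s(panel$matrix, fdr_threshold = fdr_threshold,
               max_components = max_components,
               seed = (seed + 13L * j) %% 2147483647L, normalization = norm)
    sel <- res$summary$best_model
    acc <- mean(sel == panel$truth)
    per$n[j] <- length(sel); per$accuracy[j] <- acc
    truth_all <- c(truth_all, panel$truth); sel_all <- c(sel_all, sel)
    if (verbose) m3s_log("benchmark", sprintf("%-5s accuracy %.3f", mod, acc))
  }
  structure(list(overall_accuracy = mean(sel_all == truth_all),
                 per_model = per, selected = sel_all, truth = truth_all),
            class = "m3s_benchmark")
}

#' @export
print.m3s_benchmark <- function(x, ...) {
  cat(sprintf("<m3s_benchmark> overall accuracy %.4f\n", x$overall_accuracy))
  print(x$per_model, row.names = FALSE)
  invisible(x)
}

#' Outlier-feature detection benchmark
#'
#' For each (majority model, outlier model) pair, simulates a homogeneous
#' panel, replaces a minority of rows with draws from the outlier model,
#' runs the selection pipeline, and calls a feature an outlier when its
#' selected model differs from the panel's modal selected model. Accuracy
#' is the fraction of planted outliers so identified, averaged over pairs.
#'
#' @param pairs List of `c(majority, outlier)` model name pairs.
#' @param n_features Panel size (default 100, i.e. 95 + 5 at the default
#'   fraction).
#' @param outlier_fraction Fraction of planted outliers (default 0.05).
#' @param n_samples Samples per feature.
#' @param seed Integer seed.
#' @param verbose Log progress.
#' @return List of class `m3s_outlier_benchmark`: `mean_accuracy`,
#'   `per_pair` data.frame.
#' @export
m3s_outlier_benchmark <- function(pairs = default_outlier_pairs(),
                                  n_features = 100L, outlier_fraction = 0.05,
                                  n_samples = 500L, seed = 1L,
                                  verbose = TRUE) {
  per <- data.frame(majority = vapply(pairs, `[`, character(1), 1),
                    outlier = vapply(pairs, `[`, character(1), 2),
                    n_outliers = NA_integer_, detected = NA_integer_,
                    accuracy = NA_real_)
  for (j in seq_along(pairs)) {
    maj <- pairs[[j]][1]; out <- pairs[[j]][2]
    panel <- simulate_panel(models = maj, n_features_per_model = n_features,
                            n_samples = n_samples,
                            seed = (seed + 101L * j) %% 2147483647L)
    panel <- inject_outliers(panel, out, outlier_fraction,
                             seed = (seed + 211L * j) %% 2147483647L)
    norm <- if (is_count_model(maj)) "auto" else "none"
    res <- m3s(panel$matrix, seed = (seed + 307L * j) %% 2147483647L,
               normalization = norm)
    sel <- res$summary$best_model
    modal <- names(which.max(table(sel)))
    called <- sel != modal
    per$n_outliers[j] <- sum(panel$outlier_mask)
    per$detected[j] <- sum(called & panel$outlier_mask)
    per$accuracy[j] <- per$detected[j] / per$n_outliers[j]
    if (verbose)
      m3s_log("benchmark", sprintf("%s + %s outliers: %d/%d detected",
                                   maj, out, per$detected[j],
                                   per$n_outliers[j]))
  }
  structure(list(mean_accuracy = mean(per$accuracy), per_pair = per),
            class = "m3s_outlier_benchmark")
}

#' Default (majority, outlier) pairs for the outlier benchmark
#' @return List of character pairs spanning count and continuous panels.
#' @export
default_outlier_pairs <- function() {
  list(c("P", "ZIP"), c("ZIP", "P"), c("G", "MG"), c("MG", "G"),
       c("LTMG", "MG"))
}

#' @export
print.m3s_outlier_benchmark <- function(x, ...) {
  cat(sprintf("<m3s_outlier_benchmark> mean accuracy %.4f\n",
              x$mean_accuracy))
  print(x$per_pair, row.names = FALSE)
  invisible(x)
}
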