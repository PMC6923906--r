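#' Asymptotic Kolmogorov distribution upper tail
#' @param t Scaled statistic sqrt(n) * D.
#' @return P(K > t) from the alternating series.
#' @keywords internal
kolmogorov_pvalue <- function(t) {
  if (t < 1e-3) return(1)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))
  min(max(p, 0), 1)
}

# Point masses (atoms) of a fitted model: zero inflation puts pi0 at 0,
# censoring puts the sub-threshold base mass at zcut.
model_atoms <- function(model, params) {
  switch(model,
    ZIG = data.frame(loc = 0, mass = params$pi0),
    ZIMG = data.frame(loc = 0, mass = params$pi0),
    LTG = data.frame(loc = params$zcut,
                     mass = stats::pnorm(params$zcut, params$mu, params$sigma)),
    LTMG = data.frame(loc = params$zcut,
                      mass = mix_cdf(params$zcut, params$weights, params$mus,
                                     params$sigmas)),
    data.frame(loc = numeric(0), mass = numeric(0))
  )
}

#' Kolmogorov-Smirnov goodness of fit
#'
#' Supremum distance between the empirical CDF of `x` and the fitted model
#' CDF. For discrete (count) models the statistic is evaluated over the
#' integer support; for continuous models with point masses (zero inflation
#' or a censoring floor) the left limits account for the atoms. The p-value
#' comes from the asymptotic Kolmogorov distribution, which is conservative
#' for discrete support.
#'
#' @param x Data vector the fit was estimated on (or held out).
#' @param fit A converged `m3s_fit`.
#' @return List with `ks_stat` and `ks_pvalue`.
#' @export
ks_gof <- function(x, fit) {
  stopifnot(inherits(fit, "m3s_fit"))
  if (!isTRUE(fit$converged))
    stop_m3s("not_converged", "ks_gof requires a converged fit")
  n <- length(x)
  if (is_count_model(fit$model)) {
    grid <- seq(min(x) - 1, max(x))
    Fm <- model_cdf(fit$model, fit$params, grid)
    Fn <- stats::ecdf(x)(grid)
    D <- max(abs(Fn - Fm))
  } else {
    u <- sort(unique(x))
    cn <- cumsum(tabulate(match(x, u), length(u)))
    Fn_hi <- cn / n
    Fn_lo <- c(0, Fn_hi[-length(u)])
    Fm_hi <- model_cdf(fit$model, fit$params, u)
    atoms <- model_atoms(fit$model, fit$params)
    atom_mass <- numeric(length(u))
    if (nrow(atoms) > 0) {
      i <- match(atoms$loc, u)
      atom_mass[i[!is.na(i)]] <- atoms$mass[!is.na(i)]
    }
    Fm_lo <- Fm_hi - atom_mass
    D <- max(abs(Fn_hi - Fm_hi), abs(Fn_lo - Fm_lo))
  }
  list(ks_stat = D, ks_pvalue = kolmogorov_pvalue(sqrt(n) * D))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up adjustment: p_(i) * n / i, cumulative minimum from the largest
#' rank down, capped at 1.
#'
#' @param pvalues Numeric vector in \[0, 1\] (NA allowed, propagated).
#' @return Adjusted values of the same length.
#' @export
fdr_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  p <- pvalues[ok]
  if (any(p < 0 | p > 1)) stop_m3s("invalid_data", "p-values must be in [0,1]")
  n <- length(p)
  out <- rep(NA_real_, length(pvalues))
  if (n > 0) {
    o <- order(p, decreasing = TRUE)
    adj <- pmin(cummin(p[o] * n / seq(n, 1)), 1)
    out[ok][o] <- adj
  }
  out
}

#' Candidate models admissible for a data set
#'
#' Count models apply only to discretized nonnegative data on the raw
#' scale; the continuous family applies to real-valued or transformed data.
#' Zero-inflated continuous candidates are dropped when the data contain no
#' zeros (their inflation mass would be unidentifiable).
#'
#' @param chars Output of [assess_characteristics()].
#' @param transform The normalization that will be applied (see
#'   [select_normalization()]).
#' @return Character vector of model names sorted by complexity rank.
#' @export
candidate_models <- function(chars, transform = "identity") {
  stopifnot(inherits(chars, "m3s_characteristics"))
  counts_ok <- chars$discretized && chars$nonnegative &&
    !chars$has_negative_infinite
  has_zero <- chars$zero_fraction > 0
  cont <- if (has_zero) c("G", "ZIG", "LTG", "MG", "ZIMG", "LTMG")
          else c("G", "LTG", "MG", "LTMG")
  out <- if (counts_ok) c("P", "NB", "ZIP", "ZINB", "BP", cont) else cont
  if (!has_zero) out <- setdiff(out, c("ZIP", "ZINB"))
  out[order(model_rank(out))]
}

#' Most parsimonious adequately fitting model
#'
#' Among fits whose KS FDR exceeds the threshold, the one with minimal
#' complexity rank wins; rank ties go first to a family preferred by the
#' Mann-Whitney peak-count adjudication (if any), then to the larger KS
#' p-value, then to fewer peaks. When no model passes, the fit with the
#' largest KS p-value is reported as provisional with `adequate = FALSE`.
#'
#' @param fits Named list of `m3s_fit` objects with `ks_fdr` filled.
#' @param fdr_threshold Passing threshold (default 0.1).
#' @param prefer Character vector of model names that win rank ties, in
#'   preference order.
#' @return List with `best_model`, `adequate`.
#' @export
select_best <- function(fits, fdr_threshold = 0.1, prefer = character(0)) {
  fits <- Filter(function(f) !is.null(f) && isTRUE(f$converged), fits)
  if (length(fits) == 0L) stop_m3s("invalid_data", "empty fit table")
  nm <- vapply(fits, `[[`, character(1), "model")
  fdr <- vapply(fits, `[[`, numeric(1), "ks_fdr")
  pv <- vapply(fits, `[[`, numeric(1), "ks_pvalue")
  pass <- !is.na(fdr) & fdr > fdr_threshold
  if (!any(pass)) {
    return(list(best_model = unname(nm[which.max(pv)]), adequate = FALSE))
  }
  rk <- model_rank(nm)
  cand <- which(pass & rk == min(rk[pass]))
  if (length(cand) > 1L) {
    pref <- intersect(prefer, nm[cand])
    if (length(pref) > 0L) {
      cand <- cand[nm[cand] == pref[1]]
    } else {
      cand <- cand[order(-pv[cand],
                         vapply(fits[cand], peak_count, integer(1)))]
    }
  }
  list(best_model = unname(nm[cand[1]]), adequate = TRUE)
}

#' One-sided Mann-Whitney test for systematically fewer peaks
#'
#' Tests H1: values in `a` are stochastically smaller than values in `b`,
#' using the normal approximation with tie correction and continuity
#' correction. Degenerate comparisons (zero variance, i.e. total ties)
#' return 0.5.
#'
#' @param a,b Integer vectors of per-gene fitted peak counts.
#' @return One-sided p-value.
#' @export
peak_parsimony_test <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L)
    stop_m3s("invalid_data", "both peak-count vectors must be nonempty")
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(c(a, b))
  tie_term <- sum(ties^3 - ties)
  v <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  if (v <= 0) return(0.5)
  z <- (U - mu + 0.5) / sqrt(v)
  stats::pnorm(z)
}

#' Per-gene model selection for an expression matrix
#'
#' The main routine: assesses data characteristics, chooses and applies a
#' normalization, fits every admissible candidate model to every gene
#' (count models on the raw counts, continuous models on the transformed
#' values), computes KS goodness of fit, adjusts p-values per model across
#' genes by Benjamini-Hochberg, and picks the most parsimonious adequately
#' fitting model per gene. When at least two of the mixture families
#' (MG/ZIMG/LTMG) pass for 20+ genes, a one-sided Mann-Whitney test on
#' their per-gene peak counts decides which family wins rank ties.
#'
#' @param matrix Gene x sample matrix (rows = genes), >= 10 samples.
#' @param fdr_threshold KS FDR passing threshold (default 0.1).
#' @param max_components Mixture component cap (default 5).
#' @param seed Integer seed; all per-gene fitting seeds derive from it.
#' @param normalization `"auto"` or an explicit transform (`"none"` is an
#'   alias for `"identity"`).
#' @param models Optional subset of candidate model names to consider.
#' @param bootstrap_ks Replace the asymptotic KS p-value by a parametric
#'   bootstrap p-value (slow; `n_boot` refits per gene and model).
#' @param n_boot Bootstrap replicates when `bootstrap_ks = TRUE`.
#' @return Object of class `m3s_result`: a list with `summary` (data.frame
#'   gene/best_model/n_peaks/adequate), `fits` (per-gene named fit lists),
#'   `normalization`, `characteristics`, `preferred_family`.
#' @export
m3s <- function(matrix, fdr_threshold = 0.1, max_components = 5L, seed = 1L,
                normalization = "auto", models = NULL,
                bootstrap_ks = FALSE, n_boot = 200L) {
  m <- as.matrix(matrix)
  if (nrow(m) < 1L) stop_m3s("invalid_data", "matrix must contain >= 1 gene")
  if (ncol(m) < 10L) stop_m3s("too_few_samples",
                              "matrix must contain >= 10 samples")
  genes <- rownames(m) %||% paste0("gene", seq_len(nrow(m)))
  chars <- assess_characteristics(m)
  if (identical(normalization, "none")) normalization <- "identity"
  choice <- if (identical(normalization, "auto")) select_normalization(chars)
            else match.arg(normalization, NORMALIZATIONS)
  tm <- apply_normalization(m, choice)
  cand <- candidate_models(chars, choice)
  if (!is.null(models)) cand <- cand[cand %in% models]
  if (length(cand) == 0L) stop_m3s("invalid_data", "no candidate models")
  counts_ok <- chars$discretized && chars$nonnegative &&
    !chars$has_negative_infinite

  fits <- vector("list", nrow(m))
  for (i in seq_len(nrow(m))) {
    raw <- m[i, ]
    trans <- tm[i, ]
    gene_seed <- (seed + 7919L * i) %% 2147483647L
    gfits <- list()
    for (mod in cand) {
      xx <- if (is_count_model(mod)) raw else trans
      if (!counts_ok && is_count_model(mod)) next
      if (MODEL_TABLE$zero_inflated[match(mod, MODEL_TABLE$model)] &&
          !any(xx == 0)) next
      f <- tryCatch(
        fit_model(xx, mod, max_components = max_components, seed = gene_seed),
        m3s_error = function(e) NULL)
      if (is.null(f) || !isTRUE(f$converged)) { gfits[[mod]] <- f; next }
      ks <- ks_gof(xx, f)
      f$ks_stat <- ks$ks_stat
      if (bootstrap_ks) {
        f$ks_pvalue <- bootstrap_ks_pvalue(xx, f, n_boot, max_components,
                                           gene_seed)
      } else {
        f$ks_pvalue <- ks$ks_pvalue
      }
      gfits[[mod]] <- f
    }
    fits[[i]] <- gfits
  }

  # BH per model across genes
  for (mod in cand) {
    pv <- vapply(fits, function(g) {
      f <- g[[mod]]
      if (is.null(f) || !isTRUE(f$converged)) NA_real_ else f$ks_pvalue
    }, numeric(1))
    fdr <- fdr_adjust(pv)
    for (i in seq_along(fits)) {
      if (!is.null(fits[[i]][[mod]])) fits[[i]][[mod]]$ks_fdr <- fdr[i]
    }
  }

  prefer <- adjudicate_mixture_family(fits, fdr_threshold)

  sel <- lapply(fits, select_best, fdr_threshold = fdr_threshold,
                prefer = prefer)
  best <- vapply(sel, `[[`, character(1), "best_model")
  adequate <- vapply(sel, `[[`, logical(1), "adequate")
  n_peaks <- vapply(seq_along(fits), function(i) {
    peak_count(fits[[i]][[best[i]]])
  }, integer(1))

  structure(list(
    summary = data.frame(gene = genes, best_model = best, n_peaks = n_peaks,
                         adequate = adequate, stringsAsFactors = FALSE),
    fits = stats::setNames(fits, genes),
    normalization = choice,
    characteristics = chars,
    preferred_family = prefer,
    fdr_threshold = fdr_threshold
  ), class = "m3s_result")
}

# Mann-Whitney adjudication between same-rank mixture families: when two
# mixture families both pass the FDR rule for >= 20 genes, the family
# fitting significantly fewer peaks (p < 0.05) is preferred at rank ties.
adjudicate_mixture_family <- function(fits, fdr_threshold,
                                      min_genes = 20L, alpha = 0.05) {
  fams <- c("MG", "ZIMG", "LTMG")
  pairs <- utils::combn(fams, 2, simplify = FALSE)
  prefer <- character(0)
  for (pr in pairs) {
    if (model_rank(pr[1]) != model_rank(pr[2])) next
    both <- vapply(fits, function(g) {
      f1 <- g[[pr[1]]]; f2 <- g[[pr[2]]]
      !is.null(f1) && !is.null(f2) && isTRUE(f1$converged) &&
        isTRUE(f2$converged) && !is.na(f1$ks_fdr) && !is.na(f2$ks_fdr) &&
        f1$ks_fdr > fdr_threshold && f2$ks_fdr > fdr_threshold
    }, logical(1))
    if (sum(both) < min_genes) next
    pk1 <- vapply(fits[both], function(g) peak_count(g[[pr[1]]]), integer(1))
    pk2 <- vapply(fits[both], function(g) peak_count(g[[pr[2]]]), integer(1))
    if (peak_parsimony_test(pk1, pk2) < alpha) prefer <- c(prefer, pr[1])
    else if (peak_parsimony_test(pk2, pk1) < alpha) prefer <- c(prefer, pr[2])
  }
  unique(prefer)
}

# Parametric bootstrap (Lilliefors-corrected) KS p-value: refit the same
# model on data simulated from the fitted parameters and compare statistics.
bootstrap_ks_pvalue <- function(x, fit, n_boot, max_components, seed) {
  d_obs <- ks_gof(x, fit)$ks_stat
  d_boot <- vapply(seq_len(n_boot), function(b) {
    xb <- model_sample(fit$model, fit$params, length(x),
                       seed = (seed + b) %% 2147483647L)
    fb <- tryCatch(fit_model(xb, fit$model, max_components = max_components,
                             seed = seed), m3s_error = function(e) NULL)
    if (is.null(fb) || !isTRUE(fb$converged)) return(NA_real_)
    ks_gof(xb, fb)$ks_stat
  }, numeric(1))
  d_boot <- d_boot[!is.na(d_boot)]
  (1 + sum(d_boot >= d_obs)) / (1 + length(d_boot))
}

#' @export
print.m3s_result <- function(x, ...) {
  cat(sprintf("<m3s_result> %d genes, normalization=%s\n",
              nrow(x$summary), x$normalization))
  print(table(x$summary$best_model))
  invisible(x)
}
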