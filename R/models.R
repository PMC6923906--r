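#' Candidate model registry
#'
#' The eleven candidate distributions, ordered by model complexity. Models
#' sharing a complexity rank are alternatives at the same parsimony level:
#' P < {NB, G} < ZIP < {ZINB, ZIG, LTG} < BP < MG < {ZIMG, LTMG}.
#'
#' @format A data.frame with columns `model`, `rank`, `type` (`"count"` or
#'   `"continuous"`) and `zero_inflated`.
#' @export
MODEL_TABLE <- data.frame(
  model = c("P", "NB", "G", "ZIP", "ZINB", "ZIG", "LTG", "BP", "MG",
            "ZIMG", "LTMG"),
  rank  = c(1L, 2L, 2L, 3L, 4L, 4L, 4L, 5L, 6L, 7L, 7L),
  type  = c("count", "count", "continuous", "count", "count", "continuous",
            "continuous", "count", "continuous", "continuous", "continuous"),
  zero_inflated = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE,
                    FALSE, TRUE, FALSE),
  stringsAsFactors = FALSE
)

#' All candidate model names
#' @return Character vector of the 11 model names in complexity order.
#' @export
model_names <- function() MODEL_TABLE$model

#' Complexity rank of a model
#'
#' @param model Model name (one of [model_names()]).
#' @return Integer rank; smaller is more parsimonious.
#' @export
model_rank <- function(model) {
  i <- match(model, MODEL_TABLE$model)
  if (anyNA(i)) stop_m3s("unknown_model", "unknown model: ",
                         paste(model[is.na(i)], collapse = ", "))
  MODEL_TABLE$rank[i]
}

is_count_model <- function(model) {
  MODEL_TABLE$type[match(model, MODEL_TABLE$model)] == "count"
}

is_mixture_model <- function(model) model %in% c("MG", "ZIMG", "LTMG")

#' Typed error constructor used across the package
#'
#' @param class Error subclass (prefixed `m3s_error_<class>`).
#' @param ... Message parts, pasted together.
#' @keywords internal
stop_m3s <- function(class, ...) {
  stop(structure(
    class = c(paste0("m3s_error_", class), "m3s_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

#' Validate a parameter list for a model
#'
#' Checks positivity of scales/rates, `pi0` in \[0,1\], mixture weights
#' summing to one, and consistent component counts.
#'
#' @param model Model name.
#' @param params Named list of parameters (see [fit_model()] for the fields
#'   used by each model).
#' @return `params`, invisibly, after validation.
#' @export
validate_params <- function(model, params) {
  bad <- function(...) stop_m3s("invalid_params", "model ", model, ": ", ...)
  need <- function(nm) {
    if (is.null(params[[nm]])) bad("missing parameter '", nm, "'")
    params[[nm]]
  }
  pos <- function(nm) {
    v <- need(nm)
    if (!all(is.finite(v)) || any(v <= 0)) bad("'", nm, "' must be > 0")
    v
  }
  switch(model,
    P = pos("lambda"),
    NB = { pos("size"); p <- need("prob")
           if (p <= 0 || p >= 1) bad("'prob' must be in (0,1)") },
    G = { need("mu"); pos("sigma") },
    ZIP = { pos("lambda"); chk_pi0(params, bad) },
    ZINB = { pos("size"); p <- need("prob")
             if (p <= 0 || p >= 1) bad("'prob' must be in (0,1)")
             chk_pi0(params, bad) },
    ZIG = { need("mu"); pos("sigma"); chk_pi0(params, bad) },
    LTG = { need("mu"); pos("sigma"); need("zcut") },
    BP = { pos("alpha"); pos("beta"); pos("scale") },
    MG = chk_mix(params, bad),
    ZIMG = { chk_mix(params, bad); chk_pi0(params, bad) },
    LTMG = { chk_mix(params, bad); need("zcut") },
    bad("unknown model")
  )
  invisible(params)
}

chk_pi0 <- function(params, bad) {
  p <- params[["pi0"]]
  if (is.null(p) || !is.finite(p) || p < 0 || p > 1)
    bad("'pi0' must be in [0,1]")
  p
}

chk_mix <- function(params, bad) {
  w <- params[["weights"]]; mu <- params[["mus"]]; s <- params[["sigmas"]]
  if (is.null(w) || is.null(mu) || is.null(s))
    bad("mixture needs 'weights', 'mus', 'sigmas'")
  k <- length(w)
  if (k < 1L || length(mu) != k || length(s) != k)
    bad("weights/mus/sigmas must share length K >= 1")
  if (any(w < 0) || abs(sum(w) - 1) > 1e-8)
    bad("weights must be nonnegative and sum to 1")
  if (any(s <= 0)) bad("sigmas must be > 0")
  invisible(params)
}

#' Construct a model fit object
#'
#' Normally produced by [fit_model()]; exposed so that fits with known
#' parameters (e.g. for goodness-of-fit calibration) can be built directly.
#'
#' @param model Model name.
#' @param params Named parameter list, validated by [validate_params()].
#' @param loglik Log-likelihood (optional; `NA` when constructed by hand).
#' @param converged Logical convergence flag.
#' @return An object of class `m3s_fit`.
#' @export
model_fit <- function(model, params, loglik = NA_real_, converged = TRUE) {
  validate_params(model, params)
  n_components <- if (is_mixture_model(model)) length(params$weights) else 1L
  structure(list(model = model, params = params, loglik = loglik,
                 n_components = n_components, converged = converged,
                 ks_stat = NA_real_, ks_pvalue = NA_real_,
                 ks_fdr = NA_real_),
            class = "m3s_fit")
}

#' @export
print.m3s_fit <- function(x, ...) {
  cat(sprintf("<m3s_fit> model=%s K=%d loglik=%.4g converged=%s\n",
              x$model, x$n_components, x$loglik, x$converged))
  cat("  params:", format_params(x$params), "\n")
  if (!is.na(x$ks_stat))
    cat(sprintf("  KS D=%.4g p=%.4g fdr=%.4g\n",
                x$ks_stat, x$ks_pvalue, x$ks_fdr))
  invisible(x)
}

#' Number of non-zero peaks of a fitted model
#'
#' Mixture models contribute their Gaussian component count; for
#' zero-inflated models the inflation mass is not a peak; every unimodal
#' model has exactly one peak.
#'
#' @param fit An `m3s_fit`.
#' @return Integer peak count.
#' @export
peak_count <- function(fit) {
  stopifnot(inherits(fit, "m3s_fit"))
  if (!isTRUE(fit$converged))
    stop_m3s("not_converged", "peak_count requires a converged fit")
  if (is_mixture_model(fit$model)) fit$n_components else 1L
}

#' Serialize fitted parameters as `key=value` pairs joined by semicolons
#' @param params Named parameter list.
#' @return Single string, e.g. `"mu=1.5;sigma=0.2"`.
#' @export
format_params <- function(params) {
  paste(vapply(names(params), function(nm) {
    paste0(nm, "=", paste(signif(params[[nm]], 6), collapse = ","))
  }, character(1)), collapse = ";")
}
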