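#' Asymptotic standard errors of fitted parameters
#'
#' Observed-information standard errors: closed forms where standard
#' (Poisson, Gaussian, zero-inflated Gaussian), the inverse numerical
#' Hessian of the log-likelihood for the other low-dimensional models, and
#' well-separated-mixture approximations (complete-data information) for
#' the Gaussian mixture families, where the effective sample size of a
#' component is n times its weight (times its uncensored fraction under
#' left truncation). Unidentified directions (singular information) yield
#' `Inf`.
#'
#' @param fit A converged `m3s_fit`.
#' @param x The data the fit was estimated on.
#' @return Named list of standard errors, parallel to the checked
#'   parameters of each model (vectors for mixture components).
#' @export
fit_standard_errors <- function(fit, x) {
  n <- length(x)
  p <- fit$params
  switch(fit$model,
    P = list(lambda = sqrt(p$lambda / n)),
    G = list(mu = p$sigma / sqrt(n), sigma = p$sigma / sqrt(2 * n)),
    ZIG = {
      n1 <- max((1 - p$pi0) * n, 2)
      list(pi0 = sqrt(p$pi0 * (1 - p$pi0) / n),
           mu = p$sigma / sqrt(n1), sigma = p$sigma / sqrt(2 * n1))
    },
    NB = hessian_se(fit, x, c("size", "mu")),
    ZIP = hessian_se(fit, x, c("pi0", "lambda")),
    ZINB = hessian_se(fit, x, c("pi0", "size", "mu")),
    LTG = hessian_se(fit, x, c("mu", "sigma")),
    BP = hessian_se(fit, x, c("alpha", "beta", "scale")),
    MG = mixture_se(p, n),
    ZIMG = c(mixture_se(p, (1 - p$pi0) * n),
             list(pi0 = sqrt(p$pi0 * (1 - p$pi0) / n))),
    LTMG = {
      fobs <- 1 - stats::pnorm(p$zcut, p$mus, p$sigmas)
      mixture_se(p, n, fobs)
    }
  )
}

mixture_se <- function(p, n, fobs = rep(1, length(p$weights))) {
  nk <- pmax(n * p$weights * fobs, 1e-8)
  list(weights = sqrt(p$weights * (1 - p$weights) / n),
       mus = p$sigmas / sqrt(nk),
       sigmas = p$sigmas / sqrt(2 * nk))
}

# SEs from the inverse numerical Hessian of the log-likelihood on the
# natural scale; NB/ZINB are re-expressed in (size, mu).
hessian_se <- function(fit, x, par_names) {
  p <- fit$params
  if (fit$model %in% c("NB", "ZINB")) p$mu <- p$size * (1 - p$prob) / p$prob
  theta <- unlist(p[par_names])
  ll <- function(th) {
    q <- p
    for (i in seq_along(par_names)) q[[par_names[i]]] <- th[i]
    if (fit$model %in% c("NB", "ZINB")) q$prob <- q$size / (q$size + q$mu)
    f <- fit; f$params <- q
    val <- try(model_loglik(f, x), silent = TRUE)
    if (inherits(val, "try-error") || !is.finite(val)) NA_real_ else val
  }
  H <- num_hessian(ll, theta)
  se <- rep(Inf, length(theta))
  V <- try(solve(-H), silent = TRUE)
  if (!inherits(V, "try-error")) {
    d <- diag(V)
    se[d > 0] <- sqrt(d[d > 0])
  }
  stats::setNames(as.list(se), par_names)
}

# Central-difference Hessian with per-coordinate relative steps.
num_hessian <- function(f, theta) {
  k <- length(theta)
  h <- pmax(abs(theta), 1e-3) * 1e-4
  H <- matrix(NA_real_, k, k)
  f0 <- f(theta)
  for (i in seq_len(k)) {
    for (j in i:k) {
      ei <- ej <- numeric(k); ei[i] <- h[i]; ej[j] <- h[j]
      if (i == j) {
        H[i, i] <- (f(theta + ei) - 2 * f0 + f(theta - ei)) / h[i]^2
      } else {
        H[i, j] <- H[j, i] <-
          (f(theta + ei + ej) - f(theta + ei - ej) -
             f(theta - ei + ej) + f(theta - ei - ej)) / (4 * h[i] * h[j])
      }
    }
  }
  H
}
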