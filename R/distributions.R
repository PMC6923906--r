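#' Gauss-Jacobi quadrature nodes and weights
#'
#' Golub-Welsch construction for the weight (1-x)^a (1+x)^b on \[-1, 1\]:
#' nodes are the eigenvalues of the symmetric tridiagonal Jacobi matrix of
#' the three-term recurrence, weights are mu0 times the squared first
#' components of the eigenvectors.
#'
#' @param n Number of nodes.
#' @param a,b Exponents of the weight function; both must exceed -1.
#' @return List with `nodes` and `weights`.
#' @keywords internal
gauss_jacobi <- function(n, a, b) {
  if (a <= -1 || b <= -1) stop_m3s("invalid_params", "Jacobi exponents must exceed -1")
  k <- seq_len(n - 1L)
  ab <- a + b
  diag0 <- c((b - a) / (ab + 2),
             (b^2 - a^2) / ((2 * k + ab) * (2 * k + ab + 2)))
  beta1 <- 4 * (a + 1) * (b + 1) / ((ab + 2)^2 * (ab + 3))
  bk <- if (n > 2L) {
    kk <- 2:(n - 1L)
    4 * kk * (kk + a) * (kk + b) * (kk + ab) /
      ((2 * kk + ab)^2 * ((2 * kk + ab)^2 - 1))
  } else numeric(0)
  off <- sqrt(c(beta1, bk)[seq_len(n - 1L)])
  J <- diag(diag0, n, n)
  if (n > 1L) {
    J[cbind(1:(n - 1L), 2:n)] <- off
    J[cbind(2:n, 1:(n - 1L))] <- off
  }
  e <- eigen(J, symmetric = TRUE)
  mu0 <- exp((ab + 1) * log(2) + lgamma(a + 1) + lgamma(b + 1) -
               lgamma(ab + 2))
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = (mu0 * e$vectors[1, ]^2)[ord])
}

# Quadrature rule for averaging over Beta(alpha, beta): returns p in (0,1)
# and weights summing to 1 (the Beta normalizer is folded in).
bp_quad <- function(alpha, beta, order = 50L) {
  gj <- gauss_jacobi(order, a = beta - 1, b = alpha - 1)
  # guard against eigenvalues numerically straying outside [-1, 1]
  p <- pmin(pmax((1 + gj$nodes) / 2, 1e-12), 1 - 1e-12)
  # the Beta normalizer cancels on renormalization (and can underflow for
  # large shapes), so normalize the raw weights directly
  list(p = p, w = gj$weights / sum(gj$weights))
}

#' Beta-Poisson probability mass function
#'
#' P(X = k) for X ~ Poisson(scale * p) with p ~ Beta(alpha, beta), the
#' two-state transcriptional bursting model. The Beta mixing integral is
#' evaluated by Gauss-Jacobi quadrature.
#'
#' @param x Nonnegative integer quantiles.
#' @param alpha,beta Beta shape parameters.
#' @param scale Maximum Poisson rate (burst size scale).
#' @param order Quadrature order (default 50).
#' @param log Return log-probabilities.
#' @return Numeric vector of probabilities.
#' @export
dbp <- function(x, alpha, beta, scale, order = 50L, log = FALSE) {
  q <- bp_quad(alpha, beta, order)
  rates <- scale * q$p
  pm <- stats::dpois(rep(x, each = order), rep_len(rates, order * length(x)))
  pr <- pmax(as.numeric(q$w %*% matrix(pm, nrow = order)), 0)
  if (log) base::log(pr) else pr
}

pbp <- function(q, alpha, beta, scale, order = 50L) {
  qq <- bp_quad(alpha, beta, order)
  k <- floor(q)
  rates <- scale * qq$p
  pm <- stats::ppois(rep(k, each = order), rep_len(rates, order * length(k)))
  out <- as.numeric(qq$w %*% matrix(pm, nrow = order))
  out[k < 0] <- 0
  out
}

mix_pdf <- function(x, weights, mus, sigmas, log = FALSE) {
  d <- rowSums(matrix(vapply(seq_along(weights), function(k) {
    weights[k] * stats::dnorm(x, mus[k], sigmas[k])
  }, numeric(length(x))), nrow = length(x)))
  if (log) base::log(d) else d
}

mix_cdf <- function(q, weights, mus, sigmas) {
  rowSums(matrix(vapply(seq_along(weights), function(k) {
    weights[k] * stats::pnorm(q, mus[k], sigmas[k])
  }, numeric(length(q))), nrow = length(q)))
}

#' Model cumulative distribution function
#'
#' CDF of any of the eleven candidate models. Zero-inflated models place a
#' point mass `pi0` at zero on top of the base law; left-truncated models
#' use censoring semantics: all mass below `zcut` is collapsed onto `zcut`,
#' so the distribution is supported on \[zcut, Inf) and F(q) = 0 below zcut,
#' F(q) = F_base(q) at and above it.
#'
#' @param model Model name.
#' @param params Named parameter list (validated).
#' @param q Numeric vector of quantiles.
#' @return Numeric vector of probabilities, nondecreasing in `q`.
#' @export
model_cdf <- function(model, params, q) {
  validate_params(model, params)
  p <- params
  base <- switch(model,
    P    = stats::ppois(floor(q), p$lambda),
    NB   = stats::pnbinom(floor(q), size = p$size, prob = p$prob),
    G    = stats::pnorm(q, p$mu, p$sigma),
    ZIP  = stats::ppois(floor(q), p$lambda),
    ZINB = stats::pnbinom(floor(q), size = p$size, prob = p$prob),
    ZIG  = stats::pnorm(q, p$mu, p$sigma),
    LTG  = ifelse(q < p$zcut, 0, stats::pnorm(q, p$mu, p$sigma)),
    BP   = pbp(q, p$alpha, p$beta, p$scale, order = p$order %||% 50L),
    MG   = mix_cdf(q, p$weights, p$mus, p$sigmas),
    ZIMG = mix_cdf(q, p$weights, p$mus, p$sigmas),
    LTMG = ifelse(q < p$zcut, 0, mix_cdf(q, p$weights, p$mus, p$sigmas))
  )
  if (isTRUE(MODEL_TABLE$zero_inflated[match(model, MODEL_TABLE$model)])) {
    pi0 <- p$pi0
    base <- (1 - pi0) * base + pi0 * as.numeric(q >= 0)
  }
  pmin(pmax(base, 0), 1)
}

#' Model density / probability mass function
#'
#' For zero-inflated continuous models the value at exactly zero is the
#' point mass `pi0` (not a density); elsewhere it is the continuous density
#' scaled by `1 - pi0`. For left-truncated models the value at `zcut` is the
#' censored mass F_base(zcut).
#'
#' @inheritParams model_cdf
#' @param x Numeric vector of quantiles.
#' @param log Return log values.
#' @return Numeric vector.
#' @export
model_density <- function(model, params, x, log = FALSE) {
  validate_params(model, params)
  p <- params
  d <- switch(model,
    P    = stats::dpois(x, p$lambda),
    NB   = stats::dnbinom(x, size = p$size, prob = p$prob),
    G    = stats::dnorm(x, p$mu, p$sigma),
    ZIP  = ifelse(x == 0, p$pi0 + (1 - p$pi0) * stats::dpois(0, p$lambda),
                  (1 - p$pi0) * stats::dpois(x, p$lambda)),
    ZINB = ifelse(x == 0,
                  p$pi0 + (1 - p$pi0) * stats::dnbinom(0, size = p$size, prob = p$prob),
                  (1 - p$pi0) * stats::dnbinom(x, size = p$size, prob = p$prob)),
    ZIG  = ifelse(x == 0, p$pi0, (1 - p$pi0) * stats::dnorm(x, p$mu, p$sigma)),
    LTG  = ifelse(x < p$zcut, 0,
                  ifelse(x == p$zcut, stats::pnorm(p$zcut, p$mu, p$sigma),
                         stats::dnorm(x, p$mu, p$sigma))),
    BP   = dbp(x, p$alpha, p$beta, p$scale, order = p$order %||% 50L),
    MG   = mix_pdf(x, p$weights, p$mus, p$sigmas),
    ZIMG = ifelse(x == 0, p$pi0,
                  (1 - p$pi0) * mix_pdf(x, p$weights, p$mus, p$sigmas)),
    LTMG = ifelse(x < p$zcut, 0,
                  ifelse(x == p$zcut, mix_cdf(p$zcut, p$weights, p$mus, p$sigmas),
                         mix_pdf(x, p$weights, p$mus, p$sigmas)))
  )
  if (log) base::log(d) else d
}

#' Draw i.i.d. samples from a candidate model
#'
#' Zero-inflated models draw a `pi0` coin and then the base law; BP draws
#' p ~ Beta(alpha, beta) then Poisson(scale * p); left-truncated models draw
#' from the base mixture and either censor draws below `zcut` to `zcut`
#' (default, emulating a saturated detection floor) or reject them.
#'
#' @inheritParams model_cdf
#' @param n Number of draws.
#' @param seed Integer seed; sampling never touches the global RNG stream.
#' @param lt_mode `"censor"` (default) or `"reject"` for LTG/LTMG.
#' @return Numeric vector of length `n`.
#' @export
model_sample <- function(model, params, n, seed, lt_mode = c("censor", "reject")) {
  validate_params(model, params)
  lt_mode <- match.arg(lt_mode)
  if (n < 1) stop_m3s("invalid_params", "n must be >= 1")
  p <- params
  withr::with_seed(seed, {
    base_draw <- function(m) switch(model,
      P    = , ZIP  = stats::rpois(m, p$lambda),
      NB   = , ZINB = stats::rnbinom(m, size = p$size, prob = p$prob),
      G    = , ZIG  = stats::rnorm(m, p$mu, p$sigma),
      LTG  = stats::rnorm(m, p$mu, p$sigma),
      BP   = stats::rpois(m, p$scale * stats::rbeta(m, p$alpha, p$beta)),
      MG   = , ZIMG = , LTMG = {
        k <- sample.int(length(p$weights), m, replace = TRUE, prob = p$weights)
        stats::rnorm(m, p$mus[k], p$sigmas[k])
      })
    x <- base_draw(n)
    if (model %in% c("ZIP", "ZINB", "ZIG", "ZIMG"))
      x[stats::runif(n) < p$pi0] <- 0
    if (model %in% c("LTG", "LTMG")) {
      if (lt_mode == "censor") {
        x[x < p$zcut] <- p$zcut
      } else {
        while (any(low <- x < p$zcut)) x[low] <- base_draw(sum(low))
      }
    }
    x
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
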