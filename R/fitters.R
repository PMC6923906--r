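#' Fit a candidate model to an expression vector
#'
#' Maximum-likelihood estimation (closed form where available, otherwise
#' EM or numerical optimization). For the Gaussian mixture families the
#' number of components is chosen by BIC over 1..`max_components`, each EM
#' started from k-means with 5 restarts. For LTG/LTMG, observations at or
#' below `zcut` are treated as left-censored at `zcut` in the likelihood.
#'
#' @param x Numeric data vector, length >= 10.
#' @param model Model name (see [model_names()]).
#' @param max_components Upper bound on mixture components (default 5).
#' @param zcut Left-censoring point for LTG/LTMG; `NULL` means the minimum
#'   observed value (the experimental resolution floor).
#' @param seed Integer seed controlling k-means restarts; fitting never
#'   touches the global RNG stream.
#' @return An object of class `m3s_fit`.
#' @export
fit_model <- function(x, model, max_components = 5L, zcut = NULL, seed = 1L) {
  if (length(x) < 10L)
    stop_m3s("too_few_samples", "need at least 10 observations, got ", length(x))
  if (anyNA(x) || any(!is.finite(x)))
    stop_m3s("invalid_data", "data must be finite and non-missing")
  check_support(x, model)
  fit <- switch(model,
    P    = fit_pois(x),
    NB   = fit_nb(x),
    G    = fit_gauss(x),
    ZIP  = fit_zip(x),
    ZINB = fit_zinb(x),
    ZIG  = fit_zig(x),
    LTG  = fit_ltg(x, zcut),
    BP   = fit_bp(x),
    MG   = fit_mg(x, max_components, seed),
    ZIMG = fit_zimg(x, max_components, seed),
    LTMG = fit_ltmg(x, max_components, zcut, seed),
    stop_m3s("unknown_model", "unknown model: ", model)
  )
  fit
}

check_support <- function(x, model) {
  if (is_count_model(model)) {
    if (any(x < 0) || any(x != floor(x)))
      stop_m3s("unsupported_data",
               model, " requires nonnegative integer counts")
  }
  if (model %in% c("ZIP", "ZINB", "ZIG", "ZIMG") && !any(x == 0))
    stop_m3s("unsupported_data",
             model, " requires zeros (pi0 unidentifiable without them)")
}

n_params <- function(model, k = 1L) {
  switch(model,
    P = 1L, G = 2L, NB = 2L, ZIP = 2L, ZINB = 3L, ZIG = 3L, LTG = 2L,
    BP = 3L, MG = 3L * k - 1L, ZIMG = 3L * k, LTMG = 3L * k - 1L)
}

## ---- closed-form fits -----------------------------------------------------

fit_pois <- function(x) {
  lambda <- max(mean(x), 1e-8)
  model_fit("P", list(lambda = lambda),
            loglik = sum(stats::dpois(x, lambda, log = TRUE)))
}

fit_gauss <- function(x) {
  mu <- mean(x)
  sigma <- max(sqrt(mean((x - mu)^2)), 1e-4)
  model_fit("G", list(mu = mu, sigma = sigma),
            loglik = sum(stats::dnorm(x, mu, sigma, log = TRUE)))
}

## ---- negative binomial: Newton on the log-size profile likelihood ---------

nb_profile_ll <- function(log_size, x, mu) {
  size <- exp(log_size)
  sum(lgamma(x + size)) - length(x) * lgamma(size) +
    length(x) * size * log(size / (size + mu)) +
    sum(x) * log(mu / (size + mu))
}

fit_nb <- function(x) {
  mu <- max(mean(x), 1e-8)
  v <- stats::var(x)
  # method-of-moments start; underdispersed data pushes size to the cap
  theta0 <- if (v > mu) log(mu^2 / (v - mu)) else log(1e4)
  theta <- theta0
  conv <- FALSE
  for (i in 1:50) {
    h <- 1e-4
    f1 <- (nb_profile_ll(theta + h, x, mu) - nb_profile_ll(theta - h, x, mu)) / (2 * h)
    f2 <- (nb_profile_ll(theta + h, x, mu) - 2 * nb_profile_ll(theta, x, mu) +
             nb_profile_ll(theta - h, x, mu)) / h^2
    if (!is.finite(f1) || !is.finite(f2) || f2 >= 0) break
    step <- f1 / f2
    theta_new <- min(max(theta - step, -7), log(1e6))
    if (abs(theta_new - theta) < 1e-10) { theta <- theta_new; conv <- TRUE; break }
    theta <- theta_new
  }
  if (!conv) { # safeguarded fallback on the same profile
    opt <- stats::optimize(nb_profile_ll, c(-7, log(1e6)), x = x, mu = mu,
                           maximum = TRUE, tol = 1e-10)
    theta <- opt$maximum
    conv <- TRUE
  }
  size <- exp(theta)
  prob <- size / (size + mu)
  model_fit("NB", list(size = size, prob = prob, mu = mu),
            loglik = sum(stats::dnbinom(x, size = size, prob = prob, log = TRUE)),
            converged = conv)
}

## ---- zero-inflated count models -------------------------------------------

zip_ll <- function(par, x) {
  pi0 <- stats::plogis(par[1]); lambda <- exp(par[2])
  n0 <- sum(x == 0); xp <- x[x > 0]
  n0 * log(pi0 + (1 - pi0) * exp(-lambda)) +
    length(xp) * log1p(-pi0) + sum(stats::dpois(xp, lambda, log = TRUE))
}

fit_zip <- function(x) {
  mu_nz <- mean(x[x > 0])
  p0 <- mean(x == 0)
  pi0_init <- max(min((p0 - exp(-mu_nz)) / (1 - exp(-mu_nz)), 0.95), 0.05)
  opt <- stats::optim(c(stats::qlogis(pi0_init), log(mu_nz)), zip_ll, x = x,
                      method = "Nelder-Mead",
                      control = list(fnscale = -1, maxit = 2000))
  model_fit("ZIP",
            list(lambda = exp(opt$par[2]), pi0 = stats::plogis(opt$par[1])),
            loglik = opt$value, converged = opt$convergence == 0L)
}

zinb_ll <- function(par, x) {
  pi0 <- stats::plogis(par[1]); size <- exp(par[2]); mu <- exp(par[3])
  prob <- size / (size + mu)
  n0 <- sum(x == 0); xp <- x[x > 0]
  n0 * log(pi0 + (1 - pi0) * prob^size) +
    length(xp) * log1p(-pi0) +
    sum(stats::dnbinom(xp, size = size, prob = prob, log = TRUE))
}

fit_zinb <- function(x) {
  xp <- x[x > 0]
  mu0 <- mean(xp); v0 <- max(stats::var(xp), mu0 + 1e-4)
  size0 <- max(mu0^2 / (v0 - mu0), 0.1)
  p0 <- max(min(mean(x == 0), 0.95), 0.05)
  opt <- stats::optim(c(stats::qlogis(p0), log(size0), log(mu0)), zinb_ll,
                      x = x, method = "Nelder-Mead",
                      control = list(fnscale = -1, maxit = 5000))
  size <- exp(opt$par[2]); mu <- exp(opt$par[3])
  model_fit("ZINB",
            list(size = size, prob = size / (size + mu), mu = mu,
                 pi0 = stats::plogis(opt$par[1])),
            loglik = opt$value, converged = opt$convergence == 0L)
}

## ---- zero-inflated Gaussian: point mass at 0 is separable ------------------

fit_zig <- function(x) {
  n0 <- sum(x == 0); xp <- x[x != 0]
  pi0 <- n0 / length(x)
  if (length(xp) < 2L)
    return(model_fit("ZIG", list(mu = 0, sigma = 1e-4, pi0 = pi0),
                     loglik = n0 * log(pi0), converged = TRUE))
  mu <- mean(xp); sigma <- max(sqrt(mean((xp - mu)^2)), 1e-4)
  ll <- n0 * log(pi0) + length(xp) * log1p(-pi0) +
    sum(stats::dnorm(xp, mu, sigma, log = TRUE))
  model_fit("ZIG", list(mu = mu, sigma = sigma, pi0 = pi0), loglik = ll)
}

## ---- left-censored Gaussian ------------------------------------------------

ltg_ll <- function(par, xobs, m_cens, zcut) {
  mu <- par[1]; sigma <- exp(par[2])
  ll <- sum(stats::dnorm(xobs, mu, sigma, log = TRUE))
  if (m_cens > 0)
    ll <- ll + m_cens * stats::pnorm(zcut, mu, sigma, log.p = TRUE)
  ll
}

fit_ltg <- function(x, zcut = NULL) {
  if (is.null(zcut)) zcut <- min(x)
  cens <- x <= zcut
  xobs <- x[!cens]
  if (length(xobs) < 2L) { # (nearly) everything censored
    return(model_fit("LTG", list(mu = zcut, sigma = 1e-4, zcut = zcut),
                     loglik = 0, converged = TRUE))
  }
  opt <- stats::optim(c(mean(xobs), log(max(stats::sd(xobs), 1e-3))), ltg_ll,
                      xobs = xobs, m_cens = sum(cens), zcut = zcut,
                      method = "Nelder-Mead",
                      control = list(fnscale = -1, maxit = 2000))
  model_fit("LTG",
            list(mu = opt$par[1], sigma = exp(opt$par[2]), zcut = zcut),
            loglik = opt$value, converged = opt$convergence == 0L)
}

## ---- Beta-Poisson ----------------------------------------------------------

bp_ll <- function(par, tab_x, tab_n, order) {
  alpha <- exp(par[1]); beta <- exp(par[2]); scale <- exp(par[3])
  if (scale > 1e6 || alpha > 1e3 || beta > 1e3) return(-1e10)
  lp <- dbp(tab_x, alpha, beta, scale, order = order, log = TRUE)
  if (any(!is.finite(lp))) return(-1e10)
  sum(tab_n * lp)
}

fit_bp <- function(x, order = 50L, search_order = 24L) {
  tab <- table(x)
  tab_x <- as.numeric(names(tab)); tab_n <- as.numeric(tab)
  m <- mean(x); v <- stats::var(x)
  s0 <- max(x) * 1.25 + 1
  vp <- max((v - m) / s0^2, 1e-4)
  mp <- min(max(m / s0, 1e-3), 0.99)
  c0 <- max(mp * (1 - mp) / vp - 1, 0.05)
  starts <- list(c(log(mp * c0), log((1 - mp) * c0), log(s0)),
                 c(log(0.5), log(0.5), log(max(x) + 1)))
  # search at a cheaper quadrature order, report at the full order; the
  # second start is only tried when the first stalls
  best <- NULL
  for (st in starts) {
    opt <- try(stats::optim(st, bp_ll, tab_x = tab_x, tab_n = tab_n,
                            order = search_order, method = "Nelder-Mead",
                            control = list(fnscale = -1, maxit = 800,
                                           reltol = 1e-7)),
               silent = TRUE)
    if (inherits(opt, "try-error")) next
    if (is.null(best) || opt$value > best$value) best <- opt
    if (best$convergence == 0L) break
  }
  if (is.null(best))
    stop_m3s("fit_failed", "BP optimization failed")
  model_fit("BP",
            list(alpha = exp(best$par[1]), beta = exp(best$par[2]),
                 scale = exp(best$par[3]), order = order),
            loglik = bp_ll(best$par, tab_x, tab_n, order),
            converged = best$convergence == 0L)
}

## ---- Gaussian mixture EM (k-means init, optional left censoring) -----------

# EM for a K-component Gaussian mixture where observations flagged censored
# contribute component mass below zcut instead of a density. sigma_floor
# prevents components from collapsing onto point masses.
em_mixture <- function(x, k, cens = rep(FALSE, length(x)), zcut = -Inf,
                       sigma_floor = 1e-4, init, tol = 1e-6, max_iter = 500L,
                       freq = rep(1, length(x))) {
  n <- sum(freq)
  nr <- length(x)
  w <- init$w; mu <- init$mu; sigma <- pmax(init$sigma, sigma_floor)
  has_cens <- any(cens)
  obs <- !cens
  xo <- x[obs]; n_cens <- sum(cens)
  ll_old <- -Inf
  converged <- FALSE
  lg <- matrix(0, nr, k)
  ex <- matrix(x, nr, k)
  ex2 <- ex^2
  for (iter in seq_len(max_iter)) {
    # E-step: log responsibilities (censored rows contribute component mass
    # below zcut; observed rows the component density)
    for (j in seq_len(k)) {
      lg[obs, j] <- log(w[j]) + stats::dnorm(xo, mu[j], sigma[j], log = TRUE)
      if (has_cens)
        lg[cens, j] <- log(w[j]) + stats::pnorm(zcut, mu[j], sigma[j], log.p = TRUE)
    }
    mx <- lg[, 1]
    if (k > 1L) for (j in 2:k) mx <- pmax(mx, lg[, j])
    lse <- mx + log(rowSums(exp(lg - mx)))
    ll <- sum(freq * lse)
    g <- exp(lg - lse)
    # M-step with truncated-normal sufficient statistics for censored rows
    if (has_cens) {
      for (j in seq_len(k)) {
        a <- (zcut - mu[j]) / sigma[j]
        lam <- exp(stats::dnorm(a, log = TRUE) - stats::pnorm(a, log.p = TRUE))
        m1 <- mu[j] - sigma[j] * lam
        m2 <- sigma[j]^2 * (1 - a * lam) + 2 * mu[j] * m1 - mu[j]^2
        ex[cens, j] <- m1
        ex2[cens, j] <- m2
      }
    }
    nk <- colSums(freq * g)
    w <- pmax(nk / n, 1e-10); w <- w / sum(w)
    mu <- colSums(freq * g * ex) / pmax(nk, 1e-10)
    sigma <- pmax(sqrt(pmax(colSums(freq * g * ex2) / pmax(nk, 1e-10) - mu^2, 0)),
                  sigma_floor)
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) {
      converged <- TRUE; ll_old <- ll; break
    }
    ll_old <- ll
  }
  ord <- order(mu)
  list(w = w[ord], mu = mu[ord], sigma = sigma[ord],
       loglik = ll_old, converged = converged)
}

kmeans_inits <- function(x, k, cens, zcut, n_restarts = 5L, seed = 1L) {
  xr <- x
  if (any(cens)) xr[cens] <- zcut
  ux <- unique(xr)
  inits <- list()
  withr::with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      centers <- if (length(ux) >= k) {
        km <- suppressWarnings(stats::kmeans(xr, centers = k, iter.max = 30))
        as.numeric(km$centers)
      } else sort(stats::runif(k, min(xr), max(xr)))
      ctr <- sort(centers)
      assign_k <- apply(abs(outer(xr, ctr, "-")), 1, which.min)
      w <- tabulate(assign_k, k) / length(xr)
      s <- vapply(seq_len(k), function(j) {
        xi <- xr[assign_k == j]
        if (length(xi) > 1) stats::sd(xi) else stats::sd(xr) / k
      }, numeric(1))
      s[!is.finite(s) | s <= 0] <- max(stats::sd(xr) / k, 1e-3)
      inits[[r]] <- list(w = pmax(w, 1e-3) / sum(pmax(w, 1e-3)), mu = ctr,
                         sigma = s)
    }
  })
  # k-means on 1-d data usually converges to one solution: dedupe restarts
  keys <- vapply(inits, function(i) paste(signif(i$mu, 4), collapse = ","),
                 character(1))
  inits[!duplicated(keys)]
}

# BIC-driven fit of a (possibly censored) Gaussian mixture.
# Returns best K in 1..max_k; stops early after two consecutive BIC
# deteriorations (standard mclust-style economy).
fit_mixture_bic <- function(x, max_k, cens = rep(FALSE, length(x)),
                            zcut = -Inf, sigma_floor, npar_fun, seed = 1L) {
  n <- length(x)
  max_k <- min(max_k, length(unique(x)))
  # frequency-compress tied observations (common after log-CPM of counts);
  # untied continuous data is binned to a fine grid (width << sigma_floor)
  # before the EM: the objective only depends on (value, censored) pairs
  xr <- x
  if (length(unique(x)) > 200L) {
    step <- max(diff(range(x)) / 512, 1e-9)
    xr <- round(x / step) * step
    xr[cens] <- x[cens]
  }
  key <- paste0(xr, "_", cens)
  first <- !duplicated(key)
  ux <- xr[first]; ucens <- cens[first]
  ufreq <- as.numeric(table(factor(key, levels = key[first])))
  best <- NULL; best_bic <- Inf
  for (k in seq_len(max_k)) {
    fits <- lapply(kmeans_inits(x, k, cens, zcut, seed = seed + 1000L * k),
                   function(init) em_mixture(ux, k, ucens, zcut, sigma_floor,
                                             init, freq = ufreq))
    lls <- vapply(fits, `[[`, numeric(1), "loglik")
    f <- fits[[which.max(lls)]]
    bic <- -2 * f$loglik + npar_fun(k) * log(n)
    if (bic < best_bic) {
      best <- c(f, list(k = k)); best_bic <- bic
    } else break  # BIC deteriorated: stop (k-means inits make this reliable)
  }
  # refit the winning K on the unbinned data so reported parameters and
  # loglik are exact
  if (!identical(xr, x)) {
    f <- em_mixture(x, best$k, cens, zcut, sigma_floor,
                    list(w = best$w, mu = best$mu, sigma = best$sigma))
    best <- c(f, list(k = best$k))
  }
  best
}

# Component-sd floor: prevents EM components from collapsing onto point
# masses (which would let a continuous mixture mimic zero inflation).
default_sigma_floor <- function(x) max(1e-4, 0.1 * stats::sd(x))

fit_mg <- function(x, max_k = 5L, seed = 1L) {
  if (length(unique(x)) < 2L) { # constant vector degenerates to one point
    return(model_fit("MG", list(weights = 1, mus = x[1], sigmas = 1e-4),
                     loglik = sum(stats::dnorm(x, x[1], 1e-4, log = TRUE))))
  }
  f <- fit_mixture_bic(x, max_k, sigma_floor = default_sigma_floor(x),
                       npar_fun = function(k) 3L * k - 1L, seed = seed)
  model_fit("MG", list(weights = f$w, mus = f$mu, sigmas = f$sigma),
            loglik = f$loglik, converged = f$converged)
}

fit_zimg <- function(x, max_k = 5L, seed = 1L) {
  n0 <- sum(x == 0); xp <- x[x != 0]
  pi0 <- n0 / length(x)
  if (length(unique(xp)) < 2L)
    stop_m3s("unsupported_data", "ZIMG needs >= 2 distinct nonzero values")
  f <- fit_mixture_bic(xp, max_k, sigma_floor = default_sigma_floor(xp),
                       npar_fun = function(k) 3L * k, seed = seed)
  ll <- n0 * log(pi0) + length(xp) * log1p(-pi0) + f$loglik
  model_fit("ZIMG",
            list(weights = f$w, mus = f$mu, sigmas = f$sigma, pi0 = pi0),
            loglik = ll, converged = f$converged)
}

fit_ltmg <- function(x, max_k = 5L, zcut = NULL, seed = 1L) {
  if (is.null(zcut)) zcut <- min(x)
  cens <- x <= zcut
  if (length(unique(x[!cens])) < 2L)
    stop_m3s("unsupported_data", "LTMG needs >= 2 distinct uncensored values")
  f <- fit_mixture_bic(x, max_k, cens = cens, zcut = zcut,
                       sigma_floor = default_sigma_floor(x[!cens]),
                       npar_fun = function(k) 3L * k - 1L, seed = seed)
  model_fit("LTMG",
            list(weights = f$w, mus = f$mu, sigmas = f$sigma, zcut = zcut),
            loglik = f$loglik, converged = f$converged)
}

#' Log-likelihood of data under a fitted model
#' @param fit An `m3s_fit`.
#' @param x Data vector on the fit's scale.
#' @return Scalar log-likelihood (censoring-aware for LTG/LTMG).
#' @export
model_loglik <- function(fit, x) {
  p <- fit$params
  switch(fit$model,
    LTG = {
      cens <- x <= p$zcut
      sum(stats::dnorm(x[!cens], p$mu, p$sigma, log = TRUE)) +
        sum(cens) * stats::pnorm(p$zcut, p$mu, p$sigma, log.p = TRUE)
    },
    LTMG = {
      cens <- x <= p$zcut
      sum(log(mix_pdf(x[!cens], p$weights, p$mus, p$sigmas))) +
        sum(cens) * log(mix_cdf(p$zcut, p$weights, p$mus, p$sigmas))
    },
    sum(model_density(fit$model, p, x, log = TRUE))
  )
}
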