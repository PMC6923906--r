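# Reference parameter sets used across tests (kept well inside the
# identifiable regime so fits are stable at moderate n).
ref_params <- list(
  P = list(lambda = 5),
  NB = list(size = 2, prob = 2 / 22),
  G = list(mu = 5, sigma = 1.5),
  ZIP = list(lambda = 10, pi0 = 0.4),
  ZINB = list(size = 3, prob = 3 / 23, pi0 = 0.4),
  ZIG = list(mu = 4, sigma = 0.8, pi0 = 0.4),
  LTG = list(mu = 5, sigma = 1.2, zcut = 4),
  BP = list(alpha = 0.4, beta = 0.4, scale = 60),
  MG = list(weights = c(0.5, 0.5), mus = c(0, 6), sigmas = c(1, 1)),
  ZIMG = list(weights = c(0.5, 0.5), mus = c(2.5, 6), sigmas = c(0.6, 0.6),
              pi0 = 0.4),
  LTMG = list(weights = c(0.4, 0.3, 0.3), mus = c(0.3, 4, 7),
              sigmas = c(0.8, 0.6, 0.6), zcut = 1)
)

# Brute-force empirical-vs-model KS distance on a dense grid (independent
# oracle for ks_gof on continuous models).
grid_ks <- function(x, cdf_fun, lo, hi, m = 200001L) {
  q <- seq(lo, hi, length.out = m)
  Fn <- stats::ecdf(x)(q)
  max(abs(Fn - cdf_fun(q)))
}

# Exhaustive hypergeometric upper-tail oracle: enumerate all subsets of
# size `peak` from `pop` and count those overlapping `class_idx` by at
# least `overlap`.
enum_hyper <- function(overlap, peak, class_size, pop) {
  if (overlap == 0) return(1)
  sets <- utils::combn(pop, peak)
  mean(apply(sets, 2, function(s) sum(s <= class_size) >= overlap))
}
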