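---
title: "Parsimonious multi-modal model selection for expression profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parsimonious multi-modal model selection for expression profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(m3select)
```

## The model

For a gene with expression vector $x_1,\dots,x_n$ across samples,
`m3select` entertains eleven generative models. The count family covers
Poisson ($\lambda$), negative binomial (size $r$, success probability
$p$, equivalently mean $\mu = r(1-p)/p$), their zero-inflated versions
(an extra point mass $\pi_0$ at zero), and the Beta-Poisson bursting
model $X \mid p \sim \mathrm{Pois}(s\,p)$, $p \sim
\mathrm{Beta}(\alpha,\beta)$, whose U-shaped mixing density ($\alpha,
\beta < 1$) captures on/off transcription. The continuous family covers
the Gaussian, the zero-inflated Gaussian (point mass at zero plus a
Gaussian), the left-truncated Gaussian, the $K$-component Gaussian
mixture $\sum_k w_k\, \mathcal N(\mu_k,\sigma_k^2)$, and its
zero-inflated and left-truncated variants. Left truncation is handled
with *censoring* semantics: values at or below the threshold $z_{cut}$
are treated as left-censored observations whose likelihood contribution
is the component mass below $z_{cut}$, reflecting a detection floor
(saturated read-based protocols) rather than missingness.

Model complexity is ordered
$P < \{NB, G\} < ZIP < \{ZINB, ZIG, LTG\} < BP < MG < \{ZIMG, LTMG\}$,
and the selection rule is parsimony under adequacy: every admissible
model is fit by maximum likelihood, goodness of fit is measured by the
Kolmogorov–Smirnov statistic $D_n = \sup_q |F_n(q) - \hat F(q)|$,
p-values are Benjamini–Hochberg adjusted *per model across genes* (each
model's KS p-values form one testing family), and the least complex
model with adjusted p above the threshold (default 0.1) is selected.
Rank ties among $\{MG, ZIMG, LTMG\}$ are resolved at panel level: when
two of these families both pass for at least 20 genes, a one-sided
Mann–Whitney test on their per-gene peak counts prefers the family that
needs systematically fewer peaks ($p < 0.05$). This operationalizes the
idea that an unnecessary censored/inflated component is itself a
complexity cost even when the raw parameter count is tied.

### Why the FDR family is per model

The alternative — adjusting across models within a gene — mixes
statistics with wholly different null behaviours into one family and
makes a gene's selection depend on how many models were admissible for
it. Per-model pooling matches the output contract (one KS-p/FDR column
per model) and keeps the adequacy decision for model $M$ comparable
across genes. This was an open question; the per-model reading is the
implemented one.

## Normalization

Four screens on the matrix (nonnegativity, zero proportion above 5%,
discreteness, presence of $-\infty$) choose among `log`, `log1p`, `cpm`,
`log_cpm`, `log_cpm1p`, `identity`: integer counts go to
`log_cpm1p`/`log_cpm` (zeros / no zeros), positive reals to
`log1p`/`log`, anything already signed or containing $-\infty$ passes
through. CPM is per column (sample), natural logs throughout. Count
models always see the raw counts; continuous models see the transformed
scale. The 5% zero threshold is a configurable convention; nothing
downstream is sensitive to it except the `high_zero_proportion` flag
itself.

## Tunable parameters

| parameter | default | units / range | rationale |
|---|---|---|---|
| `fdr_threshold` | 0.1 | adjusted p | adequacy rule for selection |
| `max_components` | 5 | components | BIC search upper bound |
| `zcut` | min(x) | expression units | detection-floor estimate |
| zero threshold | 0.05 | fraction | "significant proportion of zeros" |
| EM tolerance | 1e-6 | relative loglik | convergence |
| EM restarts | 5 | k-means starts | multimodal likelihood |
| sigma floor | 0.1 sd(x) | expression units | see below |
| BP quadrature order | 50 | nodes | CDF accuracy |
| DE `fdr_threshold` | 0.05 | adjusted p | DE flagging |

## Numerical choices

**Mixture EM.** Initialization is k-means with $K$ centers, 5 restarts,
best final log-likelihood kept (duplicate initializations are detected
and run once). $K$ is chosen by BIC over $1..K_{max}$; the search stops
at the first BIC deterioration — with k-means initialization the BIC
curve is reliably unimodal in $K$ here, and scanning past the first
minimum doubles cost for no observed change in selection. Component
standard deviations are floored at $0.1\,\mathrm{sd}(x)$: without a
floor the likelihood is unbounded (a component collapsing onto one
point), and — more insidiously for *selection* — a near-point-mass
component lets a plain mixture mimic zero inflation, which would defeat
the parsimony comparison between MG and ZIMG. EM input is
frequency-compressed over tied values and, when more than 200 distinct
values remain, binned to a 512-point grid (bin width far below the sigma
floor); the winning $K$ is refit on the exact data so reported
parameters and log-likelihoods are unbinned.

**Censored E-step.** Under LTG/LTMG, observations at $z_{cut}$
contribute $\Phi((z_{cut}-\mu_k)/\sigma_k)$ to the mixture likelihood;
the M-step uses truncated-normal sufficient statistics
$E[X \mid X \le z_{cut}]$ and $E[X^2 \mid X \le z_{cut}]$ computed with
log-scale Mills ratios for stability.

**Beta-Poisson.** The PMF/CDF integrate the Poisson law over the Beta
density by Gauss–Jacobi quadrature with weight
$(1-t)^{\beta-1} t^{\alpha-1}$, nodes and weights from the Golub–Welsch
eigendecomposition of the Jacobi recurrence (validated against an
independent quadrature implementation and a $10^6$-draw Monte-Carlo CDF).
Order 50 is used for every reported quantity; the likelihood *search*
runs at order 24 for speed, with the final parameters re-scored at order
50. Weights are renormalized to sum to one, which cancels the Beta
normalizer and avoids underflow at large shapes. The MLE uses
Nelder-Mead on $(\log\alpha, \log\beta, \log s)$ from a
method-of-moments start.

**Kolmogorov–Smirnov.** For continuous models $D_n$ uses the standard
order-statistic formula extended with atom-aware left limits: the fitted
point masses (zero inflation at 0, censored mass at $z_{cut}$) are
subtracted when evaluating the model CDF just below an observation. For
count models the statistic is evaluated over the integer grid spanning
the data. P-values come from the asymptotic Kolmogorov series, which is
conservative on discrete support. Because parameters are estimated from
the same data, the plug-in p-values are biased upward (the Lilliefors
effect); this is accepted — it only makes the adequacy rule easier to
pass for *all* models and parsimony still orders them — and an optional
parametric bootstrap (`bootstrap_ks = TRUE`, 200 refits) provides
calibrated p-values when they matter.

**Degenerate inputs.** Constant vectors fit P (integer) or G with sigma
floored at $10^{-4}$; mixtures refuse more components than distinct
values; zero-inflated candidates are dropped for genes without zeros
(their $\pi_0$ is unidentifiable); columns with zero library size are
excluded from CPM and reported via an attribute rather than silently
dropped.

**Determinism.** Every stochastic operation takes an explicit seed and
runs under `withr::with_seed`, so the package never reads or perturbs
the caller's RNG stream; per-gene seeds are derived from the top-level
seed by fixed prime strides.

## The differential expression test

Samples are assigned to the peak with maximal posterior probability
(ties to the lower peak); zeros under zero-inflated fits and censored
values under truncated fits form label 0, read as "no significant
expression". For each gene, non-zero peak $k$ and sample class $c$, the
overlap is tested with the upper-tail hypergeometric probability
$P[X \ge \text{overlap}]$, $X \sim \mathrm{Hypergeom}(N, |c|, |k|)$, and
BH correction is applied across all (gene, peak, class) triples tested
in the call — one family, since the call is one screening experiment.
Only enrichment is tested; depletion of class $c$ appears as enrichment
of its complement. `top_peak_only` restricts to the highest peak, the
reading in which only "high expression" membership is of interest.

## What the simulation benchmark establishes

`simulate_panel()` draws homogeneous feature panels from each of the 11
models with parameters sampled from ranges in
`inst/extdata/benchmark_params.json`. The ranges are the package's
declaration of a "realistic but identifiable" world, chosen once, before
measurement, to keep adjacent families distinguishable at $n = 500$:
Poisson rates in $[2, 20]$ (well away from the NB boundary), NB size in
$[1, 4]$ (strong overdispersion), inflation masses $\pi_0 \in [0.2,
0.6]$, mixture component gaps of at least three component standard
deviations, Beta-Poisson shapes below one (bimodal bursting), and
truncation floors censoring 15–40% of the mass. The benchmark fits each
panel with the full pipeline (counts through automatic normalization;
continuous panels already on the model scale, so identity — the
round-trip contract is "with matched normalization") and scores
exact-name recovery.

A green benchmark therefore establishes: the fitters recover their own
models; the KS-FDR parsimony rule does not over-select simple models
when the data genuinely need complexity, nor complex ones when they do
not; and the Mann-Whitney adjudication correctly separates ZIMG from
LTMG on zero-inflated multi-modal data (where LTMG must spend an extra,
mostly-censored component to absorb the zero mass). It does **not**
establish performance on real data: real profiles have library-size
gradients, correlated genes, batch structure, and model misspecification
everywhere, none of which the generator emulates. The platform-shaped
generators (`simulate_platform`) reproduce three distributional
signatures (a common detection floor; cell-varying dropout; near-zero-
free multimodality) as shapes only, not as faithful protocol simulators.
Outlier detection is defined relative to a panel's *modal selected
model* — a features-vs-cohort screen, not an outlier test with
calibrated error rates.

## Known limitations

- Beta-Poisson inference inherits quadrature bias at extreme shapes; it
  is the hardest model to identify, consistent with its reputation.
- Plug-in KS p-values are anti-conservative for rejecting (conservative
  for adequacy); use the bootstrap flag for calibrated ones.
- Per-gene fitting ignores between-gene and between-cell covariance; CPM
  is the only depth adjustment offered.
- The Mann-Whitney family adjudication needs 20+ doubly-passing genes;
  below that, rank ties fall back to the larger KS p-value, which on a
  single gene is close to a coin flip between ZIMG and LTMG when both
  fit.
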