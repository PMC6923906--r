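# m3select

Gene-wise selection of the most parsimonious statistical model for
single-cell and bulk expression profiles.

## The problem

A gene's expression across hundreds of cells rarely follows one textbook
distribution. Depending on the platform and protocol it may look like
Poisson or negative binomial counts, a log-normal cloud, a zero-inflated
mixture (drop-outs), a left-censored mixture (reads saturating at a common
detection floor), or a genuinely multi-modal mixture where each peak is a
distinct transcriptional regulatory state. Downstream analyses —
differential expression above all — inherit whatever model is assumed, so
choosing it per gene, from the data, matters.

`m3select` fits **eleven candidate models** to every gene:

| model | description | data type |
|---|---|---|
| P | Poisson | counts |
| NB | negative binomial | counts |
| G | Gaussian | continuous |
| ZIP | zero-inflated Poisson | counts |
| ZINB | zero-inflated negative binomial | counts |
| ZIG | zero-inflated Gaussian | continuous |
| LTG | left-truncated (censored) Gaussian | continuous |
| BP | Beta-Poisson (transcriptional bursting) | counts |
| MG | Gaussian mixture | continuous |
| ZIMG | zero-inflated Gaussian mixture | continuous |
| LTMG | left-truncated Gaussian mixture | continuous |

and selects, per gene, the **most parsimonious model that fits**: models
are ordered by complexity

    P < {NB, G} < ZIP < {ZINB, ZIG, LTG} < BP < MG < {ZIMG, LTMG}

each fit is scored by a Kolmogorov–Smirnov goodness-of-fit statistic,
p-values are Benjamini–Hochberg adjusted per model across genes, and the
simplest model with adjusted p (FDR) above 0.1 wins. Complexity-rank ties
among the mixture families are adjudicated by a one-sided Mann–Whitney
test on per-gene peak counts: the family that explains the panel with
systematically fewer peaks is preferred.

Before fitting, the data are screened for four characteristics
(nonnegativity, zero proportion, discreteness, negative-infinite entries)
which choose among log, log(x+1), CPM, log(CPM) and log(CPM+1)
normalizations. Count models are fit on the raw counts, continuous models
on the transformed scale.

Downstream, `m3s_test()` calls differential expression by assigning every
sample to a mixture peak (zeros and censored values form a "no signal"
class 0) and testing each (peak, sample-class) pair for enrichment with an
upper-tail hypergeometric test, BH-corrected over all tested triples.

## Worked example

```r
library(m3select)

# 5 Poisson + 5 zero-inflated Poisson features, 200 cells
panel <- simulate_panel(models = c("P", "ZIP"), n_features_per_model = 5,
                        n_samples = 200, seed = 42)
res <- m3s(panel$matrix, fdr_threshold = 0.1, seed = 1)
res
#> <m3s_result> 10 genes, normalization=log_cpm1p
#>
#>   P ZIP
#>   5   5
res$fits[["f0006_ZIP"]][["ZIP"]]
#> <m3s_fit> model=ZIP K=1 loglik=-518.4 converged=TRUE
#>   params: lambda=14.5743;pi0=0.26
#>   KS D=0.02232 p=1 fdr=1
```

Every generated feature is recalled as its true model: the counts were
auto-normalized (`log_cpm1p`), all eleven candidates fit, and the
parsimony rule kept P for the pure-Poisson rows (rank 1) and escalated to
ZIP (rank 3) exactly where the extra zeros demand it. The fitted
`lambda=14.57, pi0=0.26` sit next to the generating values.

Differential expression on a bimodal gene:

```r
x <- model_sample("MG", list(weights = c(.5, .5), mus = c(1, 6),
                             sigmas = c(.5, .5)), 500, seed = 31)
m <- matrix(x, 1, dimnames = list("geneX", paste0("s", 1:500)))
sel <- m3s(m, normalization = "none", seed = 3)
sel$summary
#>    gene best_model n_peaks adequate
#> 1 geneX         MG       2     TRUE
de <- m3s_test(m, ifelse(x > 3.5, "hi", "lo"), sel)
de[de$de, c("gene", "peak", "class_name", "p_value", "fdr")]
#>    gene peak class_name       p_value           fdr
#> 1 geneX    1         lo 9.464765e-150 1.892953e-149
#> 4 geneX    2         hi 9.464765e-150 1.892953e-149
```

The low peak (1) is enriched in class "lo" and the high peak (2) in "hi";
the hypergeometric p-values are BH-adjusted over all tested
(gene, peak, class) triples and flagged at FDR < 0.05.

## Command line

```sh
Rscript inst/cli/m3s.R simulate --kind panel --out matrix.tsv --truth truth.tsv --seed 7
Rscript inst/cli/m3s.R select --input matrix.tsv --output results.tsv --fdr 0.1 --max-k 5 --seed 17
Rscript inst/cli/m3s.R test --input matrix.tsv --classes classes.tsv --output de.tsv
Rscript inst/cli/m3s.R benchmark --n-features 30 --seed 1
```

`--mtx dir/` reads a CellRanger-layout MatrixMarket directory; `--config
file.json` can preset any option; every subcommand funnels all randomness
through `--seed`.

## Vignette

`vignettes/model-selection.Rmd` documents the statistical model, every
tunable parameter with its default and rationale, what the simulation
benchmark does and does not establish, and the numerical choices
(EM initialization, BIC search, censored E-step, Gauss–Jacobi quadrature
for the Beta-Poisson CDF, KS plug-in bias).
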