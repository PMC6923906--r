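Package: m3select
Title: Multi-Modal Model Selection for Single-Cell and Bulk Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Gene-wise selection of the most parsimonious statistical model
    among eleven candidate distributions (Poisson, negative binomial,
    Gaussian, zero-inflated and left-truncated variants, Beta-Poisson and
    Gaussian mixtures) for single-cell or bulk expression profiles.
    Provides maximum-likelihood and EM fitters for every candidate,
    Kolmogorov-Smirnov goodness-of-fit with Benjamini-Hochberg FDR control,
    a complexity-ordered parsimony rule with a Mann-Whitney peak-count
    tie-break, peak-membership hypergeometric differential expression
    testing, data-driven normalization, a simulation benchmark generator,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Matrix,
    data.table,
    jsonlite,
    optparse,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
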