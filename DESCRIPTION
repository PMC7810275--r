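Package: weeddyn
Title: Density-Structured Weed Dynamics from Ordinal Coverage Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for density-structured analysis of longitudinal weed
    coverage surveys. Ordinal coverage levels observed yearly at crop-field
    sites are modelled with a mixed cumulative-link (proportional-odds)
    transition model with a site-level random intercept, fitted by marginal
    maximum likelihood using adaptive Gauss-Hermite quadrature or the
    Laplace approximation. Fitted models are turned into column-stochastic
    4x4 transition matrices per management profile, projected over multi-year
    management scenarios, and summarised through stationary distributions
    and two-phase rotation equilibria. Includes AIC-based backward model
    selection, a synthetic survey generator for parameter-recovery
    experiments, and a command-line wrapper for the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
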