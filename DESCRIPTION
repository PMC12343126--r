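Package: srdrive
Title: Population Dynamics of X-Linked Sex-Ratio Meiotic Drive Under
    Pesticide Stress
Version: 0.1.0
Authors@R:
    person("srdrive", "developers", email = "srdrive@example.org",
           role = c("aut", "cre"))
Description: Tools to study how a novel environmental stressor (pesticide
    dose) interacts with genotype-specific fitness to set the equilibrium
    frequency of an X-linked sex-ratio meiotic drive allele (SR) in a
    Drosophila-like population. Provides a synthetic-data generator for
    vial-level dose-response mortality and per-female fecundity
    experiments; binomial GLM and Poisson GLMM parametrization with
    likelihood-ratio model selection and Tukey-adjusted genotype
    contrasts; a deterministic five-genotype, non-overlapping-generations
    drive model with pre-mating mortality, genotype-specific brood sizes,
    100 percent drive efficacy and Beverton-Holt density dependence; and
    equilibrium sweeps over dose and fecundity with extinction-threshold
    detection and curve-shape diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    lme4,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
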