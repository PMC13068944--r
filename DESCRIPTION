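Package: mouthform
Title: Hierarchical Bayesian Inference of Diet-Induced Mouth-Form
    Plasticity and Transgenerational Memory
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies the probability that Pristionchus pacificus animals
    develop the predatory (eurystomatous, Eu) mouth form across
    multigenerational diet-induction and food-reversal experiments. Plate
    level Eu counts are modelled with a hierarchical beta-Bernoulli model in
    which a generation-level mode (omega) and concentration (kappa) link the
    biological replicates of one experimental group; the posterior is
    explored with a seeded Metropolis-within-Gibbs sampler and summarized by
    pooled posterior means and 95% highest-density intervals. A deterministic
    classifier turns per-generation summaries into memory-duration calls
    (none, intergenerational, transgenerational), and a synthetic plate-count
    generator emulates the induction/reversal experimental design so the
    whole pipeline is testable end to end, including simulation-based
    calibration of interval coverage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
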