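Package: foldgain
Title: Fold-Change Activation Optimization for Gene Circuit Topologies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Steady-state models, figures of merit, and curve-fitting tools for
    optimizing the fold-change activation (FCA) of gene circuits built around a
    promoter under test. Implements linear block models and nonlinear molecular
    and genetic steady-state models of open-loop, indirect coherent feedforward
    (coherent feedforward type 4), and double-negative-feedback (mutual
    inhibition) topologies; computes FCA, logarithmic sensitivity, minimum
    detection level and switching threshold from dose-response curves; fits
    monotone Hill and biphasic loop-strength response functions; and generates
    synthetic flow-cytometry-style replicate measurements (log-normal per-cell
    populations summarized by geometric means) so every analysis stage can be
    exercised end-to-end against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
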