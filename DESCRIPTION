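Package: hteval
Title: Interactive Interrogation of Health-Economic Decision Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A scriptable toolkit for interrogating health-economic decision
    models in real time: bias-adjusted random-effects meta-analysis of trial
    evidence (DerSimonian-Laird and Gibbs-sampled Bayesian modes, with
    expert-elicited additive and proportional bias adjustment), a generic
    deterministic/stochastic decision-model engine that preserves joint
    uncertainty for correlated parameters, economic post-processing
    (incremental net monetary benefit, ICER efficiency frontier with
    dominance and extended dominance, cost-effectiveness acceptability
    curves), tornado-style one-way influence analysis with a stochastic
    reference bar, and scenario management with reproducible, seeded runs.
    Ships a worked antenatal anti-D prophylaxis style example model and
    synthetic-data generators with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    data.table,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr
Config/testthat/edition: 3
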