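Package: ipmiac
Title: Intermediate Acceptance Criteria from Integrated Process Models
Version: 0.1.0
Authors@R: person("IPM", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Derives intermediate acceptance criteria (iACs) for critical
    quality attributes at each unit operation of a multi-step
    biopharmaceutical purification process. Each unit operation is described
    by a regression model of its specific clearance or yield (design-of-
    experiments models in the process parameters, load-dependence models in
    the specific load concentration, or a fitted lognormal clearance
    distribution); the models are concatenated into an integrated process
    model and propagated by Monte-Carlo simulation with process parameters
    sampled from their normal operating ranges. Out-of-specification (OOS)
    probabilities at drug substance are estimated from the simulated
    distribution using a chi-square upper confidence bound on the standard
    deviation, and acceptance criteria are obtained by parameter sensitivity
    analysis: imposed pool values are swept over a screening grid and the
    pool value whose downstream OOS probability equals a pre-defined
    threshold (default 5%) is the iAC. Includes a synthetic-process
    generator with closed-form oracles, a plausibility check against
    manufacturing data, a conventional +/- 3 standard deviation baseline,
    and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
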