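Package: ccestimands
Title: Odds-Ratio Estimands and Rate Ratios in Case-Control Studies of Closed Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calculator and simulator for the population quantities targeted by
    case-control odds ratios in a closed cohort with one-way migration from the
    unexposed to the exposed group (as under a vaccination programme or spreading
    infection). Deterministic numerical integration of piecewise-constant hazard
    cohort dynamics yields the person-time rate ratio and the matched
    (risk-set-sampled, time-stratified) and unmatched (pooled density-sampled)
    odds-ratio estimands; an individual-level Monte Carlo simulator with four
    control-sampling designs (risk-set, unmatched density, case-cohort,
    cumulative) verifies empirically which sample odds ratio is consistent for
    which population quantity. Includes closed-cohort 2x2 identities linking
    outcome odds ratios, exposure odds ratios and risk ratios under different
    control-sampling schemes, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    yaml,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
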