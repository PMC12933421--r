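Package: evactwin
Title: Digital-Twin Simulation of Theory-Driven Hurricane Evacuation
    Messaging
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Agent-based digital-twin simulator for testing crisis-message
    framing effects on hurricane evacuation compliance in zoned synthetic
    populations. Agents carry Extended Parallel Process Model and Theory of
    Planned Behavior belief constructs initialized from demographic and
    geospatial attributes; a deterministic message-to-construct mapping
    (Message Assessment Framework) activates beliefs, an appraisal gate
    separates danger-control from fear-control responses, and a logistic
    propensity rule with threshold-based action selection produces
    evacuation decisions. Includes a seeded replicated experiment protocol
    and the accompanying statistical analysis: chi-square tests of
    independence with adjusted standardized residuals, pooled framing
    compliance rates, grouped logistic regression odds ratios, and
    noncentral chi-square power computations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
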