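Package: asthmod
Title: Markov Cohort Modelling of Medication Adherence in Difficult-to-Control Asthma
Version: 1.0.0
Authors@R:
    person("Model", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A weekly-cycle Markov cohort model linking population medication
    adherence to long-term outcomes in adults with difficult-to-control asthma.
    Five health states (controlled, partially controlled, uncontrolled,
    exacerbation, dead) are simulated over a 20-year horizon; a piecewise
    exponential mapping converts an adherence rate into treatment
    effectiveness, which blends full-adherence and no-treatment (odds-ratio
    adjusted) transition probabilities. Outputs are expected exacerbations,
    life years, discounted QALYs, and discounted NHS/PSS costs, with a seeded
    probabilistic sensitivity analysis, scenario comparisons under common
    random numbers, and command-line reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
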