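Package: hardsteps
Title: Hard-Steps Models of Rare Evolutionary Transitions on Habitable
    Planets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analytic distributions, Monte Carlo simulators and inference
    tools for the hard-steps (critical-steps) model of evolution towards
    complex life on habitable planets.  Provides the conditional law of
    the m-th of n hard steps given that all n complete within the
    habitable lifetime (a scaled Beta distribution), a delayed variant
    in which "forbidden" Earth-system reorganisation periods follow some
    steps, exact and rejection samplers for conditioned step-time
    vectors, estimation of the number of hard steps from an observed
    emergence time, pre-parameterised Earth scenarios, and a command
    line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
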