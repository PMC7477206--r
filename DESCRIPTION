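Package: cvrsem
Title: Cerebrovascular Risk, Frontoparietal Network Integrity and Executive Function
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for studying how cerebrovascular risk factors relate to
    brain-network structure and executive cognitive function in healthy
    ageing cohorts. Provides a rule-based cerebrovascular risk (CVR) score,
    trial-level cognitive preprocessing with robust (median/MAD)
    normalisation, a latent-variable structural equation modelling engine
    (maximum likelihood and full-information maximum likelihood with
    standardised solutions, fit indices and nested chi-square comparisons),
    model-free sliding-window association curves, Fisher r-to-z correlation
    comparisons, multiple regression with variance-inflation diagnostics,
    percentile-bootstrap mediation, and a calibrated synthetic cohort
    generator with known ground truth for end-to-end validation.
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
    car
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
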