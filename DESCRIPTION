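Package: ichscreen
Title: Cost-Utility Modelling of Vascular Imaging Strategies in
    Intracerebral Hemorrhage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A Markov cohort decision model comparing four vascular imaging
    strategies for patients presenting with intracerebral hemorrhage: CT
    angiography for everyone, CT angiography restricted to those with a high
    or indeterminate non-contrast CT appearance, catheter angiography for
    everyone, and catheter angiography restricted by the same stratification.
    The package provides a validated parameter deck (diagnostic test
    performance, modified Rankin Scale outcome distributions, re-bleed
    probabilities, costs in 2011 USD, utilities), Bayes revision of lesion
    probability, lifetime discounted cost and quality-adjusted life-year
    accumulation over a yearly-cycle cohort model, incremental
    cost-effectiveness ratios with dominance classification, and one-way,
    two-way, threshold and probabilistic sensitivity analyses including
    cost-effectiveness acceptability curves. Synthetic stand-ins for a
    background life table and an age-to-lesion-prevalence look-up let the
    whole pipeline run self-contained.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
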