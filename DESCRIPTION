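Package: bottlebioassay
Title: Bayesian Concentration-Response Analysis for Mosquito Bottle Bioassays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of insecticide susceptibility bottle bioassays in adult
    mosquitoes. Fits a Bayesian binomial five-parameter logistic
    concentration-response model to multi-laboratory bioassay campaigns,
    estimates lethal-concentration (LC50/LC99) and oviposition-inhibition
    (OI50/OI99) endpoints with replicate-level uncertainty ranges, quantifies
    within-bioassay variability, aggregates estimates across institutions, and
    derives discriminating concentrations for resistance monitoring. Includes
    quality-control filtering with Abbott-style control-mortality correction
    and a synthetic bioassay-campaign generator with known ground-truth curves
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    rjags,
    coda,
    jsonlite,
    ggplot2,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
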