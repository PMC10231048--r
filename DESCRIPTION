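Package: psir
Title: Insecticide Resistance Surveillance for Mosquito Vectors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-support toolkit for territory-scale surveillance of
    insecticide resistance in mosquito vectors. Takes raw WHO tube/bottle
    bioassay records, larval dose-response series, synergist assays and
    genotype samples; computes control-corrected mortality, emergence
    inhibition, log-probit LC50/IE50 and resistance ratios; classifies each
    population on the 0-3 resistance scale; stratifies territories into
    Risk-of-Resistance (RiR) classes from the prevalence of resistant
    sentinel sites; and emits graded surveillance and vector-control
    recommendations. Includes sampling-design validators (sentinel-site
    counts, trap densities, breeding-site spacing, genotyping sample sizes),
    allele-detection power and tipping-point calculators, and a seeded
    generator of complete synthetic surveillance datasets with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    geosphere
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
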