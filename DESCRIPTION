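Package: cyberslug
Title: Agent-Based Simulation of Approach-Avoidance Foraging Decisions in a
    Predatory Sea-Slug
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Headless, seeded re-implementation of the Cyberslug foraging
    agent: a neuroeconomic model of approach-avoidance decision making in
    the predatory sea-slug Pleurobranchaea californica. The agent integrates
    bilateral odor sensation, Rescorla-Wagner classical conditioning of prey
    odor signatures, and a homeostatic satiation variable into a continuous
    appetitive state that switches turning responses between approach and
    avoidance. The package provides the odor-diffusion arena, prey dynamics,
    the full decision core, a batch experiment runner for learning-by-
    satiation prey-selectivity experiments, and CSV/trace outputs suitable
    for downstream statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
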