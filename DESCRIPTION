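Package: redcom
Title: Reduced Metabolic Models of Microbial Communities from Elementary
    Flux Vectors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Constraint-based modeling of multi-species microbial
    communities under balanced growth. Builds compartmented community
    models from single-species stoichiometric models, linearizes them at
    a fixed community growth rate, and implements the RedCom reduction:
    elementary flux vectors (EFVs) of each species are enumerated at the
    fixed growth rate, projected to their exchange reactions, filtered by
    a convex-dominance minimality test, and used as net-conversion
    reactions of a small linear community model. Includes a
    double-description EFV enumerator with an exact-rational brute-force
    oracle, flux variability analysis, linear-fractional yield
    optimization, iterative maximum-growth-rate search, and toy fixture
    communities with analytically known behavior.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    xml2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
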