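Package: hypersample
Title: Sampling-Design Utilities for Conditioned Latin Hypercube Surveys
Version: 0.1.0
Authors@R:
    person("Field Sampling", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for planning raster-covariate-based field surveys with
    conditioned Latin hypercube sampling (cLHS): simulated-annealing cLHS over
    a covariate stack, Kullback-Leibler divergence between sample and
    population covariate distributions, exponential-decay sample-size
    optimisation, buffered Mahalanobis-similarity relocation of inaccessible
    sites, adapted hypercube evaluation of legacy samples (aHELS) for
    allocating additional sites, and per-pixel count-of-observations (COOBS)
    coverage maps. Includes a seeded synthetic-landscape generator and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
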