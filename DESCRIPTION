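Package: weedrot
Title: Density-Structured Simulation and Bioeconomics of Herbicide-Resistant
    Black-Grass Management
Version: 0.1.0
Authors@R:
    person("Weedrot", "Developers", email = "weedrot@example.org",
           role = c("aut", "cre"))
Description: Tools for evaluating crop-rotation strategies against
    herbicide-resistant black-grass (Alopecurus myosuroides). Implements a
    density-structured population model in which the distribution of ordinal
    weed density states in a field evolves year-on-year under a hierarchical
    cumulative-logit transition model with management covariates, random
    effects for crop transition, rotation and field, and multiple imputation
    for crop transitions missing from the training data. Couples the
    simulated density trajectories to a gross-margin economic model with
    density-responsive winter-wheat yield, and compares business-as-usual,
    continuous-wheat and mitigation scenarios through opportunity and
    productivity costs at field and national scale, including 18-year
    switching sequences from a worst-case density distribution. Includes a
    synthetic-data generator emulating the field survey, resistance assay and
    management-history inputs so the full pipeline runs without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tools,
    jsonlite,
    stats,
    utils
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
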