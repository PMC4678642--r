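Package: qualflux
Title: Regulatory Steady-State Analysis Coupled to Constraint-Based Flux Modelling
Version: 0.1.0
Authors@R:
    person("qualflux", "developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analyse qualitative multi-state regulatory networks together with
    genome-scale metabolic models. Reads and writes a supported subset of
    SBML-qual and SBML (fbc v2 / COBRA notes), finds attractors of synchronous
    logical dynamics, translates attractor levels into continuous flux-bound
    constraints via user-declared state/interval equivalences, and uses them to
    constrain flux balance analysis. Provides flux variability analysis with
    warm-started re-optimisation, knockout scans across metabolic and
    regulatory components, phenotypic phase analysis, attractor censuses over
    sampled initial conditions, and time-dependent regulated FBA of batch
    cultures. Includes synthetic fixtures (lac and maltose operon toys, random
    Boolean networks) and brute-force oracles so every analysis is testable
    without external model downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    boot,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
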