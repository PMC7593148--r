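Package: chrononiche
Title: Agent-Based Simulation of Resource Competition Among Circadian-Rhythmic Organisms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An individual-based model of one or two species competing for
    limited resources on a spatial grid, where each organism's movement
    follows a cosine activity rhythm with heritable amplitude and phase-angle
    traits. Supports competitive-exclusion and coexistence experiments,
    character displacement of circadian phase, evolution of rhythm amplitude
    under time-of-day specialization, and allochronic population splitting
    under phase-assortative mating, quantified by a cross-group mating (CGM)
    statistic based on 2-means clustering of mating-window overlaps. Includes
    scenario presets, seeded batch runners, circular statistics, and tidy
    CSV/JSON output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
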