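Package: macrorich
Title: Species-Richness Hotspots, Nestedness, Co-Occurrence Nulls and
    Historical Biogeography on Gridded Range Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrated macroecological and macroevolutionary toolkit for
    explaining gridded species-richness patterns. Builds richness grids and
    presence-absence matrices from rasterized range maps; delineates
    biodiversity hotspots probabilistically with global Moran's I and local
    Getis-Ord Gi* statistics; scores nestedness (matrix temperature,
    Brualdi-Sanderson discrepancy, NODF) and checkerboard co-occurrence
    (C-score with standardized effect sizes) against fixed-rows /
    equiprobable-columns Monte-Carlo null models; relates richness to
    environmental energy with forward-stepwise OLS under AICc, spatial
    autoregressive error models, and quantile-regression constraint
    envelopes; and fits dispersal-extinction-cladogenesis (DEC and DEC+j)
    range-evolution models on dated phylogenies with biogeographic
    stochastic mapping of per-area dispersal counts. A synthetic-data module
    generates energy gradients, source-sink range sets, and simulated DEC
    histories so the whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Matrix,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
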