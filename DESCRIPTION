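Package: enmgap
Title: Ecological Niche Modeling and Conservation Gap Analysis for Island Floras
Version: 0.1.0
Authors@R:
    person("ENM", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Presence-background ecological niche modeling pipeline for
    island plant groups: maximum-entropy models with L1 regularization and
    AICc tuning over feature-class by regularization-multiplier grids,
    bootstrap replicates, clamped projection to future climate scenarios,
    binary thresholding with Cohen's kappa, MESS extrapolation surfaces,
    Levins niche breadth, endemism categorization, stacked richness and
    uncertainty maps, and protected-area gap analysis.  Includes a
    synthetic-island world generator (correlated bioclim layers, virtual
    species, clustered occurrence sampling, scenario deltas, conservation
    polygons) so the whole pipeline runs and is tested without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
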