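Package: aquapanel
Title: Diversity, Expansion and Trend Analysis of Aquaculture Production Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing long-run aquaculture production statistics
    organised as year x country x species panels, such as FAO FishStatJ
    exports. Provides Pareto dominance decomposition of annual production
    into dominant, relevant and minor entities, Shannon diversity series,
    per-species geographic profiling (persistence, diffusiveness,
    geographical expansion rate, quadrant classification, relative
    productivity), trend fitting with forecasting, growth-rate and
    carrying-capacity summaries, species-by-year succession matrices with
    row scaling and hierarchical clustering, and a seeded synthetic panel
    generator that reproduces the statistical structure of such data for
    testing and method development.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
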