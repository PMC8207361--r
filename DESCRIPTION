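Package: fishscape
Title: Individual-Based Simulation of Age-Structured Fish Populations on
    Heterogeneous Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates an age-structured fish population moving on a
    two-dimensional lattice landscape under age-specific habitat preference
    and density-dependent habitat selection (a basin-model suitability rule),
    with Leslie-matrix demography and size-selective fishing applied to older
    age classes. Provides gradient and fragmented landscape generators,
    scaled-Beta niche curves for strong and weak ontogenetic habitat
    preference, a stochastic annual cycle of synchronous movement,
    reproduction and survival, population-level summary indices (Shannon age
    diversity and the spatial coefficient of variation of abundance), and the
    regression analyses that relate spatial variability to fishing-driven age
    truncation across factorial scenario grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    optparse,
    jsonlite
Config/testthat/edition: 3
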