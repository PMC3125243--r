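Package: netcomm
Title: Individual-Based Gene-Network Metacommunity Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Individual-based simulation of two competing species in a
    three-patch metacommunity, where each species' limiting quantitative
    trait is encoded by a heritable single-input Boolean gene network
    (random or scale-free topology). Provides the genome model
    (construction, state evaluation, phenotype scaling), sexual
    reproduction with recombination and mutation, Gaussian stabilizing
    selection against an evolving per-patch resource quality, passive
    dispersal with inter-patch mortality, a deterministic per-generation
    scheduler, a factorial experiment driver, and summary metrics
    (mid-parent heritability, coexistence, persistence time, 0.9 K
    ecosystem-function proxies, trait-environment mismatch) with
    convenience model fits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    igraph
Config/testthat/edition: 3
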