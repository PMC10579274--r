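Package: thermoqsip
Title: Quantitative Stable Isotope Probing of Hot-Spring Sediment Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative stable isotope probing (qSIP) of microbial
    communities: a forward simulator of DNA buoyant-density gradient
    experiments with known per-taxon ground truth, estimation of 13C atom
    fraction excess from fraction-level qPCR and amplicon observations with
    bootstrap confidence intervals and emergent-taxon detection,
    absolute-abundance and diversity statistics, phylogenetic-signal tests
    (Moran's I, Abouheif's Cmean, correlograms), Spearman co-occurrence
    networks with module detection, and genome-informed classification of
    primary substrate utilizers versus cross-feeders.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    utils,
    vegan,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
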