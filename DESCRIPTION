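Package: biofoot
Title: Landscape-Scale Biodiversity Footprints of Commodity Cultivation
Version: 0.1.0
Authors@R: person("Biofoot", "Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A tested pipeline for landscape-scale biodiversity impact
    assessment of a cultivated commodity (cocoa) and its export supply
    chain. Harmonizes a categorical land-cover map into a nine-class
    land-use raster via priority-ordered allocation rules, models mean
    species abundance (MSA) under land-use, infrastructure and
    fragmentation pressures with a GLOBIO-style multiplicative structure,
    computes a counterfactual (pre-cultivation) intactness loss, weights
    it by a rarity index derived from rarity-weighted species richness,
    and attributes the resulting biodiversity-weighted hectares to
    subnational trade flows, including production-share handling of
    untraced export volume. Ships a seeded synthetic-landscape generator
    so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
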