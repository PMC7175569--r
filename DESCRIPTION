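Package: felidgen
Title: Spatially Explicit Demogenetic Simulation for Solitary Felids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Individual-based, spatially explicit simulator of the coupled
    demographic and neutral-genetic ("demogenetic") dynamics of solitary
    felid populations, exemplified by Eurasian lynx. Generates neutral
    three-patch landscapes by midpoint displacement, simulates daily
    dispersal as a habitat-dependent correlated walk parameterised along a
    shy-bold movement-syndrome axis, models territory-based settlement,
    reproduction and mortality on a felid-year cycle, tracks 12 diploid
    microsatellite loci under Mendelian inheritance with stepwise mutation,
    and reports observed heterozygosity, F-statistics, patch growth factors,
    colonisation success and pedigree-based founder contributions for
    reintroduction scenarios.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
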