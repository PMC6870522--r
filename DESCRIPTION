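Package: ncmtools
Title: Neutral Community Assembly Analysis for Microbiome OTU Tables
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for testing neutral community assembly in host-associated
    microbiomes from amplicon OTU tables. Provides readers for classic
    tab-separated and BIOM-JSON OTU tables, the standard abundance-based OTU
    retention filters, alpha and beta diversity metrics (Shannon, richness,
    Whittaker beta, Aitchison, Bray-Curtis, Faith's PD, exact rarefaction),
    permutation statistics (PERMANOVA, PCoA, canonical discriminant
    classification, Kruskal-Wallis with Conover post-hoc), and a full
    implementation of the Sloan occurrence-abundance neutral model:
    migration-rate estimation by bounded nonlinear least squares, Wilson
    confidence bands, classification of taxa as neutral or under
    positive/negative host selection, and comparison against a binomial
    sampling null. A synthetic-data module simulates neutral local
    communities (stationary beta shortcut and an explicit Hubbell
    birth-death-immigration chain), selected taxa, and diet metabarcoding
    tables for end-to-end testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    optparse
Config/testthat/edition: 3
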