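Package: allotrait
Title: Hierarchical Bayesian Tree Allometry and Phylogenetically
    Controlled Trait Correlations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Fits hierarchical Bayesian height-diameter and crown
    radius-diameter allometries for co-occurring tree species (linearized
    power law and an asymptotic alternative, compared by WAIC), then
    propagates posterior uncertainty into phylogenetically controlled
    Kendall rank correlations between species functional traits and
    allometric parameters or expected tree dimensions at reference stem
    diameters. Includes a synthetic-data generator (Yule phylogenies,
    Brownian-motion traits, trait-coupled allometric parameters and
    individual tree measurements) so the whole pipeline can be exercised
    and calibrated without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    coda,
    rjags,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
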