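Package: rhizonet
Title: Community Assembly and Co-Occurrence Network Analysis for
    Microbiome Count Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for amplicon-style microbiome studies:
    rarefaction and alpha/beta diversity with permutation tests,
    phylogenetic null-model inference of community assembly processes
    (beta-MNTD, beta-NTI, Bray-Curtis-based Raup-Crick, five-process
    classification, normalized stochasticity ratio), SparCC correlation
    inference on compositional counts with permutation significance, and
    network ecology (topology reports, modules, within-module degree and
    participation-coefficient keystone roles, natural-connectivity
    robustness curves, community cohesion). Includes a synthetic community
    generator with known assembly scenarios and correlation structure so
    every stage has a recovery test.
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
    tools,
    utils,
    vegan,
    yaml
Suggests:
    biomformat,
    picante,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
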