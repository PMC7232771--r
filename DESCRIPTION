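Package: seascapeConn
Title: Seascape Genetics: Biophysical Connectivity and Population Genetic Concordance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for seascape-genetic inference in coastal seas: synthetic
    seascape construction (grids, divergence-free current fields, environmental
    gradients), Lagrangian particle tracking of passively drifting propagules,
    normalized dispersal connectivity matrices with multigenerational
    stepping-stone accumulation, dispersal-barrier clustering at tunable
    crossing-probability thresholds, Wright-Fisher stepping-stone genotype
    simulation, population-genetic summary statistics (Weir-Cockerham FST,
    expected heterozygosity, FIS, genic exact tests, identity-by-state
    distances, metric MDS), and genetic-versus-biophysical concordance analyses
    (Mantel tests, isolation-by-distance regressions, heterozygosity-environment
    models with variance-inflation screening).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    tools,
    utils,
    yaml,
    vcfR,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
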