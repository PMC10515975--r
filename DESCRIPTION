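Package: plustree
Title: Plus-Tree Screening from Terrestrial Laser Scanning and SSR Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens superior ("plus") trees in plantations that have lost
    seed-source information. Segments individual trees from terrestrial
    laser scanning point clouds (progressive densification ground filtering,
    DEM/CHM normalization, trunk detection and shortest-path crown
    assignment), extracts growth structural characteristics (height, DBH
    from a DBSCAN-clustered stem slice, crown width/area/volume, height to
    living crown, cylinder-model trunk volume) and component biomass from
    ln-linear allometric models. Computes SSR genetic diversity statistics
    (Na, Ne, Ho, He, Shannon's I, PIC, Hardy-Weinberg tests), Nei genetic
    distances, neighbour-joining dendrograms, a Gibbs-sampler admixture
    model with Evanno delta-K model choice, and ranks trees within genetic
    groups by a contribution-weighted principal-component composite score
    to select the top fraction per group. Includes simulators for point
    cloud stands with analytic ground truth and for admixed SSR genotypes,
    so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    data.table,
    igraph,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
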