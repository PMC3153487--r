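Package: clumpshare
Title: Reaction-Diffusion Modelling of Cooperative Sucrose Digestion in
    Yeast Cell Clumps
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates the sharing of invertase-liberated monosaccharides
    among budding yeast cells growing in microtiter wells, comparing an
    isolated cell with the central cell of a multicellular clump. The
    model couples Michaelis-Menten sucrose hydrolysis at the cell wall,
    glucose-regulated invertase expression, saturable hexose import, and
    spherically symmetric diffusion of sucrose and glucose solved with an
    implicit finite-volume scheme. Also provides the plate-assay
    statistics used on such experiments (adjusted Wald binomial confidence
    intervals, competition log-ratio estimates with Student-t intervals,
    OD-to-cell-count calibration with a clump correction factor) and
    synthetic-data generators for well-growth and two-genotype
    competition datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
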