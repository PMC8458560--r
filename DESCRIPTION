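Package: tcellscan
Title: Naive T Cell Motility Statistics and In Silico Dendritic Cell Encounter Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for analysing 3D naive T cell tracks from intravital
    two-photon microscopy and for simulating T cell scanning of the lymph
    node T cell zone. Computes step speeds, turning and plane angles, mean
    displacement versus square-root time and the motility coefficient;
    generates synthetic measured-like cohorts from a speed-coupled
    correlated random walk; synthesizes long tracks by joint resampling of
    (speed, turning angle, plane angle) step triplets with a
    roughness-matching exchange algorithm; and runs an agent-based
    simulation of T cell encounters with static dendritic cells in a
    spherical T cell zone with freeze-on-contact and residency accounting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
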