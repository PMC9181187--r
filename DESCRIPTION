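Package: corneaSM
Title: Simulation and Analysis of Specular Microscopy of the Corneal
    Endothelium
Version: 0.1.0
Authors@R:
    person("Eye Bank", "Imaging Group", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quality grading and endothelial cell density (ECD)
    estimation of donor-cornea specular microscopy, built around a fully
    synthetic, ground-truthed endothelial mosaic generator. Implements
    clipped Voronoi reconstruction of cell borders from pointed centers,
    the variable-frame center method for ECD, SMAS-style four-category
    image-quality grading, Hoechst-style nuclei detection as a gold
    standard, and normality-gated paired statistics with Holm-Sidak
    adjustment for longitudinal storage series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
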