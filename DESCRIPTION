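Package: zipperjunction
Title: Conductance-Trace Analysis and Zipper-Model Simulation of
    Self-Restoring DNA Single-Molecule Junctions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for single-molecule break-junction experiments on DNA
    duplexes in the zipper configuration, where the duplex clamps the
    electrode nanogap perpendicular to its axis and junction rupture
    proceeds by unzipping. Provides seeded generators for synthetic
    conductance-displacement trace ensembles, bimodal current-voltage sweep
    ensembles and consecutive-trace series; trace processing (displacement
    origin convention, per-trace-histogram plateau filtering, 1D/2D
    conductance histograms with Gaussian peak fitting, two-segment
    tunnelling decay-constant extraction); transition voltage spectroscopy
    via Fowler-Nordheim transforms; self-restoration statistics (dwell
    lengths, formation judgements, longest runs, joint-probability
    permutation tests); and a sequence-dependent one-dimensional DNA-zipper
    kinetic Monte Carlo model of a tethered duplex under pull-hold-return
    protocols, reproducing partial unzipping at tens of piconewtons and
    spontaneous reannealing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
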