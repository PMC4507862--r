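Package: cgforge
Title: Systematic Coarse-Graining by Relative-Entropy and Simplex Optimization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A self-contained toolkit for bottom-up coarse-graining of simple
    fluids.  Pair potentials between coarse-grained beads are represented
    either as uniform cubic B-splines (knot values on an even grid) or as a
    modified Lennard-Jones form with a cosine-squared smoothed attraction and
    a shifted Gaussian bump.  Spline potentials are optimized by
    Newton-Raphson minimization of the relative entropy between a reference
    ensemble and the coarse-grained model; the analytic form is optimized by
    a downhill-simplex search on a radial-distribution-function plus pressure
    penalty.  The package ships its own NVT Metropolis Monte-Carlo sampler
    for point particles and small rigid molecules in a cubic periodic box,
    center-of-mass mapping, cell-list and brute-force neighbor search,
    radial distribution function analysis with a frame-parallel merge
    contract, and synthetic reference-fluid generators for end-to-end
    self-target experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    parallel,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
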