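Package: msfweb
Title: Master Stability Functions and Pattern-Formation Robustness in
    Food-Web Metacommunities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Linear stability analysis of food-web metacommunities on
    patch networks. Classifies linearized reaction-diffusion systems as
    stable, unstable, or pattern-forming from the master stability
    function (dispersion relation) of the mode Jacobian P - kappa*C,
    where P is the local trophic Jacobian and C the linearized dispersal
    (cross-diffusion) response matrix. Provides the four classic
    three-species interaction motifs with type-II functional responses,
    samplers for local parameters and connectivity matrices with optional
    adaptive sign constraints (prey tracking, predator avoidance),
    nested Monte-Carlo estimation of local, spatial and total robustness
    of each dynamical class, niche-model random food webs for
    species-rich metacommunities, and an independent patch-network
    verification layer based on graph-Laplacian eigenmode decomposition.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
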