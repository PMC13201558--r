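Package: echowss
Title: Ultrafast Ultrasound Flow Simulation and Wall Shear Stress Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and estimation toolkit for ultrafast-Doppler wall shear
    stress (WSS) imaging in coronary-artery-scale vessels. Generates parametric
    2D vessel phantoms (straight, eccentric stenosis, malapposed stent struts)
    with analytic steady flow fields and closed-form wall shear references;
    synthesizes beamformed IQ ensembles of advected microbubble-like scatterers
    with static clutter and noise; implements singular-value-decomposition
    clutter filtering on the Casorati matrix, transverse-oscillation vector
    velocity estimation by lag-one autocorrelation, loess profile smoothing,
    zero-velocity wall detection with locally weighted quadratic contour
    fitting, and pseudo-spectral (Fourier sine series) wall shear stress
    mapping; and provides the regional comparison metrics (segment thirds,
    MAPE, Spearman correlation, spatial variance, Welch group test) used to
    evaluate such pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
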