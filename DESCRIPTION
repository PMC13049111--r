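Package: pbeq
Title: Lead Equivalence of X-Ray Protective Equipment from Transmission
    Measurements
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Evaluates the lead equivalence of x-ray radiation protective
    equipment (aprons, mobile screens, shields) from a single pair of
    air-kerma readings. A calibrated semi-empirical tungsten-anode
    spectrum model and bundled photon attenuation data convert measured
    narrow- or broad-beam transmission into an equivalent thickness of
    lead, with a buildup-factor correction for broad-beam geometries.
    Includes beam-quality metrics (aluminium HVL, homogeneity, lead TVL),
    a photon Monte Carlo for scatter spectra from a water phantom and for
    lead K-fluorescence buildup, and a grid-search designer for
    scatter-mimicking primary tube beams.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
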