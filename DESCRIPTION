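Package: lvsa
Title: Coupled Left-Ventricle and Systemic-Artery Pulse-Wave Simulator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale simulator of ventricular-arterial coupling. A
    one-dimensional cross-sectional-area-averaged model of the 24 large
    systemic arteries is advanced with a two-step Lax-Wendroff scheme and
    closed at every terminal vessel by the root impedance of an asymmetric
    structured tree of small arteries. During systole the arterial network
    is coupled, through pressure/flow matching at the aortic root, to a
    reduced-order contracting left ventricle: a thick-walled incompressible
    spherical shell with Holzapfel-Ogden passive myocardium and a
    phenomenological active-tension twitch. The package reproduces baseline
    haemodynamics (brachial pressures, aortic flow, pressure-volume loops),
    four pathological scenarios (arterial stiffening, vascular-bed
    rarefaction, myocardial stiffening, increased contractility), and
    ventricular-arterial coupling indices (effective arterial elastance,
    end-systolic elastance, ESPVR).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    pracma
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
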