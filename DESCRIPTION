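Package: dxblink
Title: Diffracted X-Ray Blinking and Tracking Analysis
Version: 0.1.0
Authors@R:
    person("dxblink", "developers", email = "dxblink@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for time-resolved X-ray diffraction movies of
    protein-attached gold nanocrystals. Implements diffracted X-ray blinking
    (DXB): per-pixel intensity autocorrelation with constrained exponential
    fitting and conversion of decay constants to rotational diffusion
    coefficients; and diffracted X-ray tracking (DXT): diffraction-spot
    detection, trajectory linking, angular (theta/chi) displacement statistics
    and Gaussian peak extraction. Ships a synthetic diffraction-movie
    simulator (rotational Brownian nanocrystal orientations rendered through a
    Gaussian rocking curve onto a flat detector) with full ground truth, so
    every analysis stage is testable by parameter recovery, plus
    nonparametric (Brunner-Munzel) and Student's t two-sample comparisons,
    multi-page TIFF movie input/output and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
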