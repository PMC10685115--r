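Package: coneratios
Title: Spatial Cone-Excitation Ratios and Relational Colour Constancy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates operational colour-constancy experiments on
    hyperspectral scenes. Renders effective spectral reflectance cubes
    under Planckian illuminants sampled uniformly in reciprocal
    temperature, computes LMS cone excitations and spatial
    cone-excitation ratios, estimates the mean relative deviation (MRD)
    of ratios across illuminant changes by Monte-Carlo pair sampling,
    constructs ratio-corrected stimuli by per-cone-class through-origin
    regression, expresses appearance in CAM02-UCS and quantifies
    generalized metamerism, generates synthetic natural-scene reflectance
    cubes, and runs a simulated two-alternative forced-choice experiment
    with inverse-cumulative-Gaussian psychometric fitting, d-prime, and
    BCa bootstrap confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    EBImage,
    rhdf5
Suggests:
    testthat (>= 3.0.0),
    boot,
    jsonlite,
    optparse
Config/testthat/edition: 3
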