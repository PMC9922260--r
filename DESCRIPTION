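Package: chiralcell
Title: Quantification of Actin Cytoskeleton Chirality in Micropatterned
    Cells and Microcultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Measures left-right (chiral) asymmetry of the actin
    cytoskeleton in single micropattern-confined cells and in rectangular
    multicellular microcultures. Single-cell chirality is quantified by the
    tilt of radial actin fibres relative to the cell radius, measured in
    concentric annuli and projected to the cell edge via
    theta = arcsin(r*sin(theta_r)/R); collective chirality by the nematic
    director field of phase-contrast texture and by the axial orientation
    of segmented nuclei, classified as aligned via the mean resultant
    length of doubled angles. Includes the connecting statistical layer
    (bimodality testing by Gaussian versus sum-of-two-Gaussians fits,
    nonparametric group comparisons, individual-versus-collective
    correlation) and a synthetic image generator with ground-truth
    manifests for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    MASS,
    graphics,
    jsonlite,
    methods,
    minpack.lm,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
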