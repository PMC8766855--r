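Package: vigncorr
Title: Single-Image Vignetting Correction for Functional Microscopy Stacks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Retrospective, single-image correction of the vignetting
    artifact (radial falloff of brightness and contrast) in single-channel
    2-photon functional microscopy stacks. Local background brightness and
    contrast are estimated robustly on a patch grid (power-law tail removal,
    iterative symmetric trimming gated by the Shapiro-Wilk statistic), the
    spatial brightness and gain fields are modelled as 2D Gaussian surfaces
    fitted by bounded nonlinear least squares, and images are corrected with
    full, brightness-only or contrast-only formulas. Includes a synthetic
    phantom generator with known ground-truth fields and the
    center/edge/corner region statistics (pairwise Welch tests with
    Bonferroni correction, c_p, DeltaC, DeltaSTD, highly-active-cell
    overlap) used to quantify center-periphery bias of neural activity
    readouts before and after correction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tiff,
    jsonlite,
    minpack.lm,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
biocViews: Software, Preprocessing, Visualization
RoxygenNote: 7.3.3
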