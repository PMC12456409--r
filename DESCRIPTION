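Package: dcmotion
Title: Quantitative Analysis of Dendritic Cell 3D Migration, Polarity and
    Nanoscale Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the quantitative readouts of dendritic-cell
    three-dimensional migration experiments: kinematics of time-lapse cell
    tracks (velocity, mean squared displacement, Euclidean displacement),
    chemotaxis directionality with a bootstrapped group comparison of mean
    displacement angles, front-rear polarity quantification from
    multi-channel fluorescence images (rear/front intensity ratios,
    nucleus-to-edge distances, width-averaged line profiles, foci counting),
    nanocluster sizing from single-molecule localization data via the pair
    correlation function with a Gaussian-cluster model fit, and population
    migration indices for transwell and in vivo homing assays. A synthetic
    data module generates persistent-random-walk tracks, polarized cell
    images, Thomas-process point patterns and binomial migration counts
    with known ground truth for every analysis stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    minpack.lm,
    optparse,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
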