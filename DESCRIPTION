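Package: lysoscreen
Title: Simulation and Quantitative Analysis of Lysosomal Damage Screens
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end machinery for microscopy-based siRNA screens of
    lysosomal membrane damage readouts. Provides a synthetic-data generator
    that plants known ground truth (multi-channel fields with nuclei,
    LAMP1-like vesicles and marker puncta; 384-well plate layouts with
    per-gene knockdown effects; damage-response time courses; SILAC
    proximity-proteomics tables), image quantification (nucleus
    segmentation, Voronoi cell partition, multi-scale Laplacian-of-Gaussian
    puncta detection, per-object intensity measurement), per-cell
    colocalization readouts (percent marker-positive vesicles, Pearson
    correlation, puncta-count classification, nuclear/cytoplasmic ratios),
    plate-level robust z-score hit calling with pool deconvolution, and
    volcano-style classification of comparative SILAC proximity-labeling
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    mvtnorm,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
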