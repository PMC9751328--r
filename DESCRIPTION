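Package: SEMBiofilm
Title: Self-Supervised Multi-Label Classification of SEM Biofilm Image Patches
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Low-annotation analysis of scanning electron microscope (SEM)
    images of sulfate-reducing-bacteria biofilms on metal surfaces. Provides a
    synthetic SEM-like scene generator with pixel-level tri-class ground truth
    (cells, microbially-induced-corrosion byproducts, non-occluded surface),
    image preprocessing (metadata-strip cropping, CLAHE contrast enhancement,
    conditional super-resolution), sliding-window patch extraction with
    per-class object masks and multi-label ground truth, self-supervised
    representation learning with both a contrastive momentum-queue InfoNCE
    objective and a non-contrastive cross-correlation redundancy-reduction
    objective, binary-relevance downstream classifiers under linear-probe and
    fine-tuning protocols, cross-validated accuracy reporting, class
    activation maps, and per-image class-distribution heatmaps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    Rcpp,
    jsonlite,
    yaml,
    rlang
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr, optparse, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
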