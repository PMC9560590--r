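Package: dbsaudit
Title: Accuracy Auditing of Deep Brain Stimulation Electrode Placement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for auditing the spatial accuracy of deep brain
    stimulation (DBS) electrode placement from image-derived electrode
    reconstructions.  Implements boundary-distance and centroid-offset
    accuracy metrics against nucleus and motor-subnucleus targets,
    pneumocephalus volumetry and affine brain-shift quantification, a
    finite-difference volume-of-activated-tissue (VAT) model with nucleus
    overlap, a battery of the standard statistical procedures used in
    movement-disorder outcome studies, and a synthetic cohort generator
    that emulates bilateral GPi/STN implantations with known ground truth
    for end-to-end validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
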