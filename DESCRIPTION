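Package: FetalScout
Title: Fetal Head-Pose Detection from Full-Uterus MRI Scout Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Locates the fetal brain and both eyes in low-resolution
    full-uterus echo-planar (EPI) scout volumes and derives the anatomical
    left-right / posterior-anterior / inferior-superior frame that drives
    automatic slice prescription of a follow-up structural scan. Detection is
    based on slice-wise maximally stable extremal regions (MSERs),
    gestational-age-specific geometric filtering against fetal biometry
    (occipitofrontal diameter, biparietal diameter, ocular diameter),
    mean-shift clustering across slices, morphological 3D mask
    regularization, and landmark-based rigid frame construction. Includes a
    seeded synthetic phantom generator with ground truth and the matching
    evaluation metrics (success criterion, translation and rotation errors).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    EBImage,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
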