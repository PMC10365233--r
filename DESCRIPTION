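Package: tractstim
Title: Tract-Guided Programming of Subthalamic Deep Brain Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for suggesting subthalamic deep brain stimulation (DBS)
    parameters from weighted tractography. Computes the activation of the
    hyperdirect pathway (HDP) and corticospinal tract (CST) inside volumes of
    tissue activated (VTAs) around 8-contact directional leads, fits logistic
    stimulation models on monopolar-review thresholds, suggests best/worst
    stimulation levels and contacts under three strategies, and evaluates
    suggestions with balanced accuracy, permutation tests and threshold
    errors. Includes reading and writing of MRtrix track (TCK) files with
    per-streamline SIFT2-style weights, NIfTI-1 VTA masks, and a synthetic
    cohort generator so the whole pipeline runs without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    RNifti,
    rlang,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
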