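Package: orthosim
Title: Mixed-Reality Orthognathic Surgery Simulation Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Software-only re-creation of a mixed-reality orthognathic surgery
    simulator. A ground-truthed synthetic craniofacial phantom stands in for the
    patient, CT scanner, 3D dental scanner and electromagnetic tracker, and the
    package implements every computational stage of the simulation pipeline:
    detection of titanium reference-splint spheres in a CT-like volume by
    connected-component labeling, fusion of 3D-scanned dental casts onto the
    metal-artifact-corrupted CT dentition with a trimmed iterative closest point
    registration, stylus digitization and tracker-to-virtual-space calibration by
    three-point rigid (Kabsch) registration, pose-stream-driven simulation of
    sagittal splitting ramus osteotomies with rigid segment repositioning,
    diagnostic coordinate frames (mirror-symmetry mid-sagittal plane and a
    quartic-curve mandibular lower-border frame) with asymmetry reporting, a
    perspective virtual cephalogram renderer, and the repeated-repositioning
    accuracy protocol summarized with an exact Wilcoxon signed-rank test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
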