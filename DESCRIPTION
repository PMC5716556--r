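Package: dtsetup
Title: Digital Tomosynthesis Simulation and Registration for Patient Setup
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates clip-based patient setup verification with short-arc
    digital tomosynthesis (DTS). Provides digital phantoms with embedded
    surgical clips, cone-beam projection simulation, shift-and-add DTS
    reconstruction with selective-plane deblurring, synthesis of reference
    DTS volumes from a planning CT, normalized cross-correlation matching
    within a bounded search region, triangulation of two or more arcs into
    a 3D couch shift, and a sweep harness that measures registration
    accuracy against known applied shifts as a function of arc length, arc
    separation, slice spacing and clip density.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    EBImage,
    RNifti,
    jsonlite,
    yaml,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
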