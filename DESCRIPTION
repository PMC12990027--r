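Package: jawmotion
Title: Mandibular Motion Trajectories from Static Virtual Interocclusal Records
Version: 1.0.0
Authors@R:
    person("Jawmotion", "Developers", email = "jawmotion@example.org",
           role = c("aut", "cre"))
Description: Converts four static virtual interocclusal records (mandibular
    arch meshes scanned at maximum intercuspation, left and right
    laterotrusive, and full protrusive positions, all expressed in a common
    maxillary-anchored frame) into a continuous, time-sequenced mandibular
    motion trajectory suitable for import into dental CAD virtual
    articulators.  Provides STL mesh reading and writing (binary and ASCII),
    closed-form rigid registration (Kabsch) with an iterative-closest-point
    fallback for uncorresponded meshes, quaternion SLERP pose interpolation
    between the recorded occlusal extremes, an open XML jaw-motion export
    format (.xml / .jawMotion), a parametric synthetic dental-arch generator
    for end-to-end testing without scan data, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
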