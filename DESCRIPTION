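Package: spinefe
Title: Parameterized Scoliotic Spine Finite-Element Models from Biplanar
    Radiograph Landmarks
Version: 0.1.0
Authors@R:
    person("spinefe", "developers", email = "spinefe@example.org",
           role = c("aut", "cre"))
Description: Builds patient-specific finite-element models of the scoliotic
    spine (C7 to L5) from landmarks digitized on posterior-anterior and
    lateral radiographs.  Per-vertebra placement parameters (superior
    posterior point, tri-axial body lengths, coronal/sagittal/transverse
    tilts, endplate wedge angles) are extracted from the two calibrated
    views and used to morph and place a parametric template vertebra via
    a Y-X-Z Euler rotation chain.  The mesher assembles hexahedral
    vertebrae, intervertebral discs (nucleus, annulus ground substance,
    criss-cross tension-only fiber trusses, cartilage endplates), seven
    tension-only ligament sets, and optional posterior instrumentation
    (pedicle-screw, rod and transverse-connector beams).  A linear-static
    solver with tension-only active-set iteration applies a flexion
    moment at C7 with the L5 inferior face fixed, and measurement and
    reporting utilities compute Cobb and thoracolumbar-kyphosis angles,
    per-axis mean absolute error against reference coordinates, segmental
    range of motion, endplate/annulus stress maxima, and pre/post
    instrumentation comparison ratios.  A synthetic-fixture generator
    produces scoliotic landmark sets with known ground truth so the whole
    pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
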