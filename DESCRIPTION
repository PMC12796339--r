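Package: implantFE
Title: Axisymmetric Finite-Element Evaluation of Bilayer Dental Implants
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Desk-scale biomechanical evaluation of a bilayered dental
    implant (solid titanium-alloy core surrounded by a porous
    hydroxyapatite/titanium composite shell) embedded in a mandibular bone
    segment.  Provides rule-of-mixtures (Voigt/Reuss) homogenization of the
    porous composite shell stiffness, a parametric axisymmetric
    quadratic-triangle mesh generator for the bone-implant assembly, a
    linear-elastic finite-element solver with von Mises stress and
    equivalent-strain recovery, Frost-mechanostat classification of
    peri-implant microstrain, and a study runner that sweeps the full
    design space of shell thickness, hydroxyapatite content, porosity and
    modulus bound to locate designs that relieve stress shielding while
    keeping interfacial bone strain in the physiological window.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
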