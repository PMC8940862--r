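Package: vasculodamage
Title: Anisotropic Hyperelastic Damage Mechanics of Arterial Tissue with
    Windkessel Hemodynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling supra-physiological degradation of
    fibre-reinforced arterial tissue and the hemodynamic quantities used to
    assess its consequences. Implements a polyconvex transversely isotropic
    strain-energy function with a two-internal-variable saturating damage
    model for the collagen fibre families (stress softening and remnant
    strain), quasi-static material-point drivers for uniaxial ramp and
    cyclic loading protocols, construction of symmetric fibre-direction
    fields on spherical aneurysm domes, a three-element Windkessel (RCR)
    outflow model with a synthetic pulsatile inflow generator, and
    time-averaged wall metrics (TAWSS, relative percentage change, von
    Mises stress, strain magnitude).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
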