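Package: dlrcalc
Title: Damage-Limited Resolution for X-Ray and Electron Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calculator for the damage-limited resolution (DLR) of X-ray and
    transmission electron microscopy of beam-sensitive (organic) specimens.
    Given a beam, an imaging mode, a feature material embedded in a matrix
    material and a resolution-dependent radiation-damage model, it computes
    the smallest detectable feature (column and voxel DLR) versus specimen
    thickness, the optimum fluence and dose, and the supporting dosimetry
    conversions between particle fluence and absorbed dose in gray units.
    Includes a registry of common cryo-specimen materials, per-modality
    contrast and collection-efficiency models (X-ray absorption and phase,
    TEM phase, bright-field and dark-field scattering contrast), Lenz-model
    electron mean free paths, and the depth-dose localization of radiolysis
    by photoelectrons and Auger electrons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    generics,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
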