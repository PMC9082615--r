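Package: surfwet
Title: Surfactant Adsorption Isotherms and Contact-Angle Modulation of
    Sessile Droplets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for surfactant adsorption at water-vapor and
    solid-water interfaces and its consequence for the contact angle of
    surfactant-laden sessile droplets. Extracts Gibbs surface-excess
    adsorption from tabulated one-dimensional density profiles, fits Langmuir
    isotherms by orthogonal distance regression with uncertainties in both
    coordinates, evaluates Kirkwood-Buff integrals from radial distribution
    functions and the resulting non-ideality correction to the
    Gibbs-adsorption (Szyszkowski-type) surface-tension reduction, models the
    exponential scaling of the adsorption coefficient with molecular surface
    area and surface wetting coefficient, and solves the surfactant-laden
    Young equation for the concentration-dependent contact-angle change.
    Includes seeded synthetic-data generators with analytically known ground
    truth that emulate molecular-dynamics density profiles, radial
    distribution functions and adsorption series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
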