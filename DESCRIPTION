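Package: picoPP
Title: Carbon-Based Productivity Modelling of Picophytoplankton Primary
    Production
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates group-specific primary production of marine
    picophytoplankton (Prochlorococcus, Synechococcus and picoeukaryotes)
    with a carbon-based productivity model: cell abundances from flow
    cytometry are converted to carbon biomass through carbon conversion
    factors, multiplied by temperature-dependent growth rates (binomial
    polynomials for Prochlorococcus ecotypes, Arrhenius forms for
    Synechococcus and picoeukaryotes) and scaled by euphotic-zone depth
    and a saturating surface-irradiance term to give volumetric and
    depth-integrated production. Includes a carbon-conversion-factor
    sensitivity analysis, reduced major axis (Model II) regression with
    bootstrap confidence intervals for validation against measured 14C
    uptake, a seeded synthetic station generator, and command-line entry
    points for estimation, validation, sensitivity and simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
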