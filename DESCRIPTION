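Package: bcehealth
Title: Benefit-Pressure-Transformation Health Index for Blue Carbon Ecotones
Version: 0.1.0
Authors@R:
    person("bcehealth", "developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes a composite Ecosystem Health Index (EHI) for blue carbon
    ecotones (mangrove, salt marsh, seagrass) on a 1-degree coastal pixel grid
    using a Benefit-Pressure-Transformation (BPT) model: normalized fitness
    indicators are aggregated into a Benefit score, compound anthropogenic and
    climatic pressures into a Pressure score, and the risk that one ecotone
    transforms into another is derived from the Sorensen overlap of
    kernel-density climatic hypervolumes.  Includes an exact Fisher-Jenks
    natural-breaks classifier, first-order Sobol global sensitivity analysis
    with bootstrap standard errors, binned latitudinal trend regressions, a
    profile-REML random-intercept mixed model, a synthetic coastal-pixel world
    generator for testing, and a subcommand command-line interface chaining the
    pipeline end to end.
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
    lme4,
    withr
Config/testthat/edition: 3
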