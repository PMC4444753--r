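Package: emugsa
Title: Two-Stage Global Sensitivity Analysis with Morris Screening and
    Gaussian Process Emulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the two-stage workflow for quantitative global
    sensitivity analysis of computationally expensive deterministic models:
    Morris elementary-effects screening with Campolongo-optimized
    trajectories, followed by variance-based sensitivity indices (main,
    total and pairwise interaction effects) computed on a Gaussian-process
    emulator trained over a maximin Latin hypercube design.  Parameter
    uncertainty spaces are built from mean/CV tables using Gaussian
    95-percent ranges with a one-standard-deviation fallback, including
    mass-balance re-parameterization of lumped compartment fractions.
    Ships a steady-state maternal-fetal thyroid-iodide stand-in model and
    analytic test functions with known sensitivity indices for validating
    the machinery, plus Lowry-plot reporting and a reproducible pipeline
    driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    lhs,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
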