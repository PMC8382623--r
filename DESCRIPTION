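Package: stentbim
Title: Budget Impact Modelling for Peripheral Drug-Eluting Stents
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A deterministic, config-driven budget impact engine comparing
    two drug-eluting stents for symptomatic lower-limb peripheral arterial
    disease over a multi-year horizon. Builds annual treated cohorts from an
    epidemiological funnel or an explicit schedule, projects clinically
    driven target-lesion revascularisations, major amputations and hospital
    bed-days under a two-cycle convention (12-month rates in a cohort's
    index year, 24-month cumulative rates the following year), costs the
    projection from both an activity-based-funding payer perspective and a
    bed-day hospital perspective, differences the two arms, and supports
    one-way scenario sweeps and state-level disaggregation. Includes
    calibration of per-patient hospital-day intensities, a synthetic-trial
    generator for parameter-recovery testing, and bit-stable CSV/JSON report
    rendering.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    yaml,
    jsonlite,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
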