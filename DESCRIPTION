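Package: trendkit
Title: Radiomics Trend Analysis for Paired CT Volumes
Version: 0.1.0
Authors@R: person("trendkit", "developers", role = c("aut", "cre"),
    email = "trendkit@example.org")
Description: Longitudinal radiomics trend analysis from paired pre- and
    post-condition CT volumes in NIfTI format. Derives body-composition
    tissue masks by intersecting body-region masks with Hounsfield-unit
    intervals, extracts per-structure intensity and volume features,
    computes per-patient absolute and relative deviations with explicit
    zero/absence edge rules, and evaluates cohort-level radiomic dynamics
    with macro-averaged relative differences and dependent paired t-tests,
    emitting tidy tables and a significance-colored overview plot. Includes
    a seeded ellipsoid phantom generator so the full pipeline is testable
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
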