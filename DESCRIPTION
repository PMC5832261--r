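Package: apmem
Title: Short-Term Action-Potential Memory and Electrical Restitution Under
    Dynamic Pacing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Single-cell study of short-term cardiac action-potential memory
    and electrical restitution in the ten Tusscher-Panfilov (2006) human
    ventricular myocyte model under dynamic pacing. Provides a compiled
    beat-by-beat simulation engine with state snapshot/restore, pacing-law
    generators (constant, uniform-random, sinusoidal-periodic, alternating,
    missing-beat and switch protocols), restitution and hysteresis metrics
    (spaces of states, Shift_CL/Shift_DI, dynamic-restitution slopes,
    principal-axis loop slopes), repolarization-stability assays
    (missing-beat recovery, alternans detection and quenching), removal of
    ion-current time-dependence by polynomial current-voltage clamps, and a
    fast beat-to-beat map surrogate for testing the analysis layer without
    ODE integration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
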