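Package: ergolever
Title: Ergonomic Assessment of Lever-Propelled Stair-Climbing Wheelchairs
    from Surface Electromyography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the ergonomic assessment of a lever-propelled
    stair-climbing wheelchair from multi-channel surface electromyography
    (sEMG).  Implements the sEMG conditioning chain (Butterworth band-pass
    filtering, rectification, moving-average envelope extraction and
    Hilbert-envelope activation detection with a minimum-duration rule), a
    weighted maximum-voluntary-contraction (MVC) statistic combining
    envelope amplitude and RMS, a Taguchi L9 fractional factorial analysis
    (main effects, interaction grids, quadratic response surfaces,
    per-muscle optima and an overall ergonomic recommendation),
    anthropometric percentile summaries with digital-human-model reach and
    turning-geometry checks, and flat-surface usability summaries.  A
    seeded synthetic-recording generator emulates pull-push lever
    propulsion cycles so the full chain is testable without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
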