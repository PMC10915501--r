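Package: knotflight
Title: Departure Timing of Shorebird Relocation Flights from High-Resolution Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to identify westward relocation-flight departures of red knots
    (Calidris canutus islandica) from regional reverse-GPS tracking data and to model
    the environmental conditions selected at departure. Implements trajectory
    filtering (speed and positional-error filters, running-median smoother), a
    rule-based departure classifier (detection-gap, core-area, straightness and
    westward-over-sea criteria with pass-through exclusion), annotation of departure
    times with tidal, solar and weather covariates (time to sunset, time to high
    tide, cloud cover, rain, pressure change, full-drift wind assistance), and a
    weighted use-availability resource selection function fitted as a binomial
    generalized additive model with penalized spline smooths, including scaled
    selection curves, bootstrap confidence intervals for smooth peaks, and a
    sensitivity analysis over the number of available points. A synthetic-data
    generator emulates the tracking system and environment with known ground truth
    so the whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mgcv,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
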