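Package: migradecide
Title: Departure, Routing and Landing Decisions of Nocturnal Songbird
    Migrants from Automated Radio-Telemetry
Version: 0.1.0
Authors@R:
    person("migradecide", "maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: A reproducible pipeline for analysing the migratory decisions
    of night-migrating songbirds tracked by an automated radio-telemetry
    (Motus-style) receiver network at a coastal stopover site.  Raw tag
    detections are filtered for false positives, segmented into sustained
    flights, classified as offshore or onshore, and screened for landings.
    Flights and stopover nights are annotated with gridded reanalysis-style
    weather covariates (wind components, temperature, pressure, cloud
    cover, station precipitation).  Three Bayesian decision models are
    provided: a proportional-hazards model of nightly departure with an
    M-spline baseline hazard, and logistic regressions with random
    intercepts for the routing (offshore versus onshore) and in-flight
    landing decisions.  A synthetic-world generator produces internally
    consistent receiver networks, weather fields and bird histories with
    known ground truth, so that every stage of the pipeline is testable
    end to end without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    splines,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
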