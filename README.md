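# migradecide

Departure, routing and landing decisions of night-migrating songbirds,
from automated radio-telemetry to Bayesian decision models — as one
tested, reproducible R pipeline.

## The problem

Small songbirds migrating along the southeastern North Sea coast in
autumn alternate stopovers with nocturnal flights. Radio-tagged birds
(uniquely coded tags, burst intervals 4.5–8 s) are detected by a
Motus-style network of coastal receiver stations, which makes three
decisions observable for each individual:

1. **Departure** — on which night does a bird leave its stopover site?
2. **Routing** — does it cross the open bight (*offshore*) or follow
   the coastline (*onshore*)?
3. **Landing** — does it interrupt its endurance flight within the
   study area?

`migradecide` converts raw detection tables into these decisions with
rule-based processing, attaches reanalysis-style weather covariates, and
fits three Bayesian models:

* a **proportional-hazards model** of the nightly departure decision,
  `h(t) = m(t)·exp(xβ + b)`, with an M-spline baseline `m(t)` (I-spline
  cumulative hazard, so nightly departure probabilities are
  `1 − exp(−exp(η)ΔI(t))`), degree-2 orthogonal-polynomial wind effects,
  24-h weather changes, cloud, rain, species contrasts and random
  intercepts for year-species and day-of-year;
* a **logistic regression** for the routing decision (offshore
  probability vs the eastward wind component at departure);
* a **logistic regression** for the landing decision (flight-level
  change in the northward wind component and cloud cover).

Reported per parameter: posterior mean, 95% credible interval, and
P(β > 0) as the fraction of posterior draws above zero.

Because the original field data are not programmatically retrievable,
the package ships a **synthetic world** (`simulate_world()`): receivers
along a German-Bight-like coastline, AR(1) gridded weather with station
rain, and bird histories generated *from the fitted decision models
themselves*, so every pipeline stage can be tested against known ground
truth. See `vignettes/methods.Rmd` for the models, generator
assumptions, and their limits.

## Worked example

```r
library(migradecide)

cfg <- sim_config(seed = 11, years = 2019,
                  n_birds = c(garden_warbler = 60, whitethroat = 60,
                              sedge_warbler = 50))
sim <- simulate_world(cfg)                                   # ~6 s
pr  <- process_tracks(sim$detections, sim$receivers, sim$deployments)
coh <- summarize_cohort(pr$first_flights, pr$landings, sim$deployments)
coh$table
#>           species  2019 onshore offshore landings
#> 1: garden_warbler    39      32        7        1
#> 2:    whitethroat    39      37        2        2
#> 3:  sedge_warbler    31      31        0        3
unlist(coh$totals)
#> flights onshore offshore offshore_pct landings tagged no_flight
#>     109     100        9          8.3        6    170        61
```

109 of 170 tagged birds yielded a detected first flight (the rest
emulate tag failure or never departing); 9 crossed the bight, and no
Sedge-Warbler-like bird did — the generator forbids it, mirroring the
structural zero in the field data. Fitting the routing model to the
annotated flights:

```r
ann  <- annotate_tracks(pr, sim$world, sim$deployments)
rfit <- fit_logistic_glmm(ann$flight_covariates, routing_spec(), seed = 1)
rfit$summary
#>          parameter estimate    q2.5   q97.5  p_gt_0
#> 1:       intercept  -2.388  -3.355  -1.452  0.000
#> 2:         u_begin  -1.077  -1.924  -0.258  0.003
```

The eastward-wind slope is recovered negative (generator truth −1.40 on
the climatological scale; the fitted value sits on the empirical scale
of self-selected departure nights, hence the mild attenuation — see the
vignette): westward winds push birds offshore. `fit_departure_model()`
and `landing_spec()` work the same way, and `run_all(cfg, "run1")`
executes simulate → process → annotate → fit → report end to end,
writing `flights.csv`, `departure_table.csv`, `table2.csv`–`table4.csv`
and a reproducibility manifest. A command-line front end lives at
`inst/cli/migradecide.R` (`simulate`, `process`, `run-all`).

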