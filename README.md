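# ebiketrainer

Personalized assist-level training for pedal-assist (PAS) electric bicycles.

A PAS e-bike adds a discrete amount of motor power to the rider's pedaling.
`ebiketrainer` uses that to turn commuting into progressive exercise: the
rider holds a *constant* power `p` matched to their ability while the motor
absorbs the route's slope variation so speed stays near an ability-matched
target `v'`. Completed rides are scored by the energy the rider supplied,
and scores accumulate along a 10-level ability ladder that raises `v'` and
`p` over time. The package is for anyone building or studying e-bike
training systems: it covers route ingestion, slope segmentation, assist
planning, heart-rate zones with a safety override, ride scoring, a
telemetry simulator, and a command-line interface.

## The model

Power to hold ground speed *s* (m/s) on grade *i* (rise over run):

```
P(s, i) = kr·M·g·s  +  ka·A·d·s·(s + w)²  +  g·i·M·s
```

with rolling coefficient `kr = 0.005`, total mass `M`, wind coefficient
`ka = 0.5`, frontal area `A`, air density `d = 1.226 kg/m³`, and signed
headwind `w`. On flat ground this collapses to `P = c1·s + c2·s³`; the two
coefficients calibrate exactly from two (speed, power) pairs of the ability
ladder (`c1 = 4.4468`, `c2 = 0.20268`), reproducing the whole ladder column
to < 0.01 W. Per segment, the motor request is `P(v', g_i) − p`, quantized
onto the bike's assist levels by midpoint intervals (ties round up); rides
score `min(rider energy in Wh, 600)` points.

See `vignette("assist-training")` for the full account: segmentation
procedure, planner edge cases (coast/reduced/sag/legal-cutoff), heart-rate
zones, the simulator's assumptions, and design rationale.

## Worked example

```r
library(ebiketrainer)

# a 6.5 km synthetic commute: gentle start, a 5.5% climb, a descent, a rise
rt <- synthesize_route(
  list(c(2000, 0.01), c(1800, 0.055), c(1200, -0.04), c(1500, 0.025)),
  step = 25, noise_sd = 1.2, seed = 20)
rt   <- compute_grades(rt, smoothing_window = 30)
segs <- segment_route(rt, bin_width = 0.02, min_length = 50)

rider <- rider_profile(mass = 78, height = 1.82, age = 34, total_points = 170)
plan  <- plan_assist(segs, rider, bike_profile(), route = rt)
plan
#> <ebt_plan> 77 segments, 6.50 km, level 4 rider @ 19 km/h
#>   predicted: 1232 s, rider 12.0 Wh, motor 46.3 Wh

tel <- simulate_ride(plan, behavior_model(speed_tracking_sd = 0.25, seed = 99),
                     hr_threshold = 0.9 * hr_max(34))
score_ride(tel, plan)
#> <ebt_score> rider 11.7 Wh + motor 46.3 Wh = 58.0 Wh -> 11.7 points (total 181.7, level 4)
```

The rider, at 170 points, sits on ability level 4 (target 19 km/h, constant
53.27 W on the flat). The planner assigns one of the bike's six assist
levels to each of the 77 slope segments so the rider's output stays near
53 W while the motor covers the climb; the simulated ride supplies 11.7 Wh
of rider energy, worth 11.7 points toward level 5 (which starts at 201
points and raises the target to 20 km/h).

## Command line

A thin wrapper over the same functions ships at
`system.file("cli/ebiketrainer.R", package = "ebiketrainer")`:

```sh
ebiketrainer.R plan  --route commute.gpx --config config.yaml --out plan.json --waypoints wpts.gpx
ebiketrainer.R ride  --plan plan.json --seed 99 --out ride.csv
ebiketrainer.R score --telemetry ride.csv --plan plan.json --out score.json
ebiketrainer.R zones --hr hr.csv --config config.yaml
ebiketrainer.R calibrate --table ladder.tsv
```

Exit codes: 0 ok, 2 input error, 3 config error. The YAML config has
`rider`, `bike`, `power_model`, `segmentation`, `simulator` blocks; unknown
keys are rejected.

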