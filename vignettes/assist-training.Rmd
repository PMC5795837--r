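---
title: "Assist-level training on pedal-assist e-bikes: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assist-level training on pedal-assist e-bikes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ebiketrainer)
```

## The training idea

A pedal-assist (PAS) e-bike adds a discrete amount of motor power to the
rider's pedaling; the assist level selects how much. ebiketrainer turns such
a bike into a progressive training device: the rider is asked to hold a
*constant* power `p` matched to their current ability, while the motor
absorbs the variation imposed by the route's slopes so that speed stays near
an ability-matched target `v'`. As the rider accumulates points from
completed rides they climb an ability ladder that raises both `v'` and `p`,
so the exercise dose grows over time without the rider ever facing a hill
unassisted.

The pipeline is: read a GPS track, compute smoothed grades, partition the
route into slope-homogeneous segments, plan one assist level per segment,
ride (or simulate), then score the ride by the energy the rider supplied.

## The power model

The power to hold ground speed $s$ (m/s) on grade $i$ (rise over run) is

$$P(s, i) = k_r M g\, s + k_a A d\, s (s + w)^2 + g\, i\, M s$$

with rolling-resistance coefficient $k_r = 0.005$, total mass $M$ (rider +
bike, kg), wind coefficient $k_a = 0.5$, frontal area $A$ (m²), air density
$d = 1.226$ kg/m³, $g = 9.8$ m/s², and signed headwind $w$ (m/s, default 0;
air speed is $s + w$). Only the flat-road groupings $c_1 = k_r M g$ (W per
m/s) and $c_2 = k_a A d$ (W per (m/s)³) enter the flat terms, which is what
makes the model calibratable from two (speed, power) pairs.

Two parameterizations are exposed:

* **physical** (`power_model_params()`): you provide $M$ and $A$, the latter
  typically from `estimate_frontal_area()`, an allometric body-surface
  scaling $A = 0.3307\,(h/1.75)^{0.725} (m/75)^{0.425}$ anchored at a
  1.75 m / 75 kg reference rider;
* **table-calibrated** (`calibrated_power_params()`,
  `default_calibrated_params()`): $c_1, c_2$ are fitted to the ability
  ladder's flat-road power column. An exact 2×2 solve on the first and last
  ladder rows gives $c_1 = 4.4468$, $c_2 = 0.20268$ and reproduces all ten
  rows to better than 0.01 W.

The two modes disagree on purpose. The calibrated coefficients imply an
effective mass of about 90.75 kg and frontal area 0.331 m², not the nominal
83 kg reference; the ladder's printed powers are internally consistent with
the former, so the calibrated mode is the default wherever ladder values
matter, and the physical mode is available when the actual rider's
parameters should govern. We also note that the rolling term is only
dimensionally meaningful with $g$ included ($k_r M g s$), which is the form
used here; with $g$ the ladder column is reproducible, without it it is not.

`speed_at_power()` inverts $P$ by bracketed root-finding (`uniroot` on
[1e-6, 60] m/s, tolerance 1e-13). For $P > 0$ the root is unique: the curve
$a s + b s^3$ with $b > 0$ is negative over the coasting dip when $a < 0$
(steep descents) and strictly increasing beyond it. $P \le 0$ returns `NA`,
the coasting sentinel — the model does not define a speed for a
gravity-powered descent, and the planner handles that case explicitly.

## Route ingestion and grades

Tracks are read from GPX 1.1 or CSV (`lat,lon,ele[,time]`). Distances use
the haversine formula on a sphere of radius 6371008.8 m; geodesic
corrections are irrelevant at sub-meter scales over ride distances.
Consecutive points closer than 0.1 m are collapsed. Grades are
rise-over-run on each inter-point step after a centered moving-average
smoothing of elevations over a 30 m distance window (default): consumer GPS
elevation noise of 1-2 m at 10-50 m spacing otherwise dominates the grade
signal. A 50 m window on a 2% ramp with 1 m noise roughly halves the mean
absolute grade error in the package's own Monte-Carlo test. Window 0 is the
identity. Grades are clipped to ±0.35, beyond any rideable road.

The generator `synthesize_route()` lays points along a great-circle heading
with piecewise-constant true grades plus seeded Gaussian elevation noise.
It emulates the geometry that matters to this package — slope structure,
point spacing, elevation noise — and nothing else: no GPS position outliers,
no stops, no turns, no barometric drift. Tests passing on synthetic routes
therefore validate the algorithms, not robustness to pathological field
recordings.

## Segmentation

Each segment later receives a single assist level, so the partition should
group adjacent steps of similar slope magnitude and not fragment. The
procedure is two deterministic passes over the per-step grades:

1. **Signed magnitude binning.** Bin edges at 0, ±`bin_width`,
   ±2·`bin_width`, …; adjacent steps in the same signed bin merge into runs.
   A grade exactly on an edge goes to the lower-magnitude bin. Runs of
   exactly zero grade are attached to the adjacent run with the smaller
   mean |grade| (ties to the preceding run), so flats inherit the sign of
   their surroundings.
2. **Short-run absorption.** Runs shorter than `min_length` are merged into
   whichever neighbor has the nearer length-weighted mean grade, shortest
   run first, until all runs are long enough (or one remains).

Defaults: `bin_width = 0.02` (2% slope classes), `min_length = 50` m — a
segment shorter than ~50 m is not worth a level change at riding speeds.
Segment grade is the length-weighted mean of its step grades, so the
reconstruction `reconstruct_profile()` integrates back to the true
elevation endpoints exactly on noise-free input. Halving `bin_width` can
only split bins, so the pre-absorption run count is monotone in the bin
resolution. The whole procedure is mirrored by a brute-force scan oracle in
the test suite over seeded random routes.

A note on tie-breaks: grades that sit exactly on a bin edge (e.g. a
constant 4% ramp with 2% bins) are assigned stably in exact arithmetic but
can fragment under real elevation jitter, since the bin boundary cuts
through the noise distribution. That is inherent to hard binning, not to
this implementation; `bin_width` should be chosen so expected grades sit
mid-bin.

## Planning assist levels

For a rider whose cumulative points place them on ladder row
(`level`, `v'`, `p`), each segment gets:

* required power $p_i = P(v', g_i)$;
* rider power `p` held constant; motor request $p'_i = p_i - p$;
* the assist level from `quantize_to_level()`: midpoint intervals over the
  bike's per-level powers, level $j$ iff
  $p'_i \in [\frac{p^l_{j-1}+p^l_j}{2}, \frac{p^l_j+p^l_{j+1}}{2})$, with
  $[0, p^l_1/2)$ mapping to level 0 and everything at or above the top
  midpoint to the top level. Left-closed intervals mean an exact midpoint
  rounds *up*; the rule is equivalent to nearest-level assignment with ties
  to the higher level.

Departures from the constant-split, each flagged in the plan: descents with
$p_i \le 0$ are coasted (`coast`: rider 0, motor 0); easy segments with
$p_i < p$ reduce the rider to $p_i$ rather than have the motor brake
(`reduced`); climbs beyond $p + $ motor maximum record the achievable speed
at full assist instead of $v'$ (`sag`); and any segment whose planned speed
exceeds the legal assistance cutoff (25 km/h default) gets motor 0
(`cutoff`) — the rider may ride faster, but unassisted. Per-level motor
powers are bike profile inputs (they are observable from battery-current
telemetry on real bikes); the default is a 750 W motor with six linearly
spaced levels. No regeneration is modeled: negative motor power is level 0.

The constant rider power `p` is taken to be the rider's own ladder row's
flat-road power. This is the one choice that makes the system self-
consistent: a flat route at target speed then requires exactly zero assist,
and progression up the ladder simultaneously raises the speed target and
the rider's workload while the motor's share shrinks.

## Heart rate

`hr_max()` is the age-predicted maximum `205.8 − 0.685·age` — a population
regression with wide individual error, used as a default, not a measurement.
Zones as fractions of HRmax: Z1 [50%, 70%), Z2 [70%, 80%), Z3 [80%, 90%),
Z4 [90%, ∞), plus a "below" bucket. The published zone scale leaves
60–70% unassigned; Z1 is extended upward to 70% here so the scale is a
partition (the minimal change, keeping Z2–Z4 as printed), and the report
carries a note to that effect. `time_in_zones()` attributes each
inter-sample interval to the zone of its left sample; fractions sum to 1 by
construction.

The safety override raises the assist level by one step when the heart rate
exceeds a threshold (default 0.9·HRmax, configurable or manual), capped at
the top level, with a 30 s hysteresis between increases; it never lowers
the level. The step size and hysteresis are this package's choices — the
underlying requirement fixes only the direction of the response.

## Scoring and progression

A completed ride is scored by the energy the rider supplied: at each
telemetry sample the demanded power is re-evaluated from the model at the
*realized* speed and segment grade, the motor's measured contribution is
subtracted, negative remainders are floored at zero (coasting is free), and
the result is integrated left-rectangle over the sample grid, in Wh. The
score is that energy capped at 600 — roughly the energy of holding 50 km/h
on the flat for an hour, taken as a human ceiling — and accrues onto the
rider's points total, from which the next ride's ability level is derived.
The cap is applied per route. Energy (Wh) is the scored quantity
throughout; a 240 Wh ride with 210 Wh of assistance scores 30 points.

## The simulator

`simulate_ride()` exists so that scoring, zone reporting and the override
are testable end-to-end without hardware. Per 1 s sample (default): speed =
the segment's planned (or sag-limited) speed plus truncated Gaussian
tracking noise; the motor delivers its active level's power clamped so
rider + motor equals the model power at the realized speed; the rider
supplies the remainder; heart rate relaxes first-order toward
`hr_rest + hr_gain · rider_power` with time constant `hr_time_constant`
(defaults 70 bpm, 0.3 bpm/W, 40 s — a fit rider's HR rises ~60 bpm at
200 W over ~2 min). These dynamics have the right qualitative shape
(exponential rise under load, recovery at rest) and no more: no VO2
kinetics, no fatigue, no cadence. An override, once triggered, persists as
a floor for the rest of the ride. Everything is deterministic given the
behavior model's seed, which is restored-RNG-scoped so simulation never
perturbs the caller's random stream.

## Numerical choices and degenerate inputs

* Root-finding: bisection-backed `uniroot`, speed tolerance 1e-13, bracket
  [1e-6, 60] m/s; the inverse identity holds to 1e-9 m/s in tests.
* Bin-edge tie-break: lower-magnitude bin, with a 1e-9 relative tolerance
  absorbing float error in `|g| / bin_width`.
* Integration: left-rectangle at the telemetry rate (1 s default);
  adequate since powers change on segment scales of tens of seconds.
* Degenerate tracks (< 2 distinct points) and missing elevations are hard
  errors naming the offending point; routes shorter than `min_length`
  return a single segment; empty segment lists reconstruct to an empty
  profile.
* All internal units are SI (m, m/s, W, s); interfaces use km/h and Wh
  where riders expect them.

## Problem sizes in the test suite

The packaged tests run on synthetic routes of 0.5-6.5 km at 20-100 m point
spacing (up to ~250 steps), 100 seeded routes for the segmentation oracle,
10^4 random (ladder, power) pairs for the quantizer oracle, and simulated
rides up to two hours at 1 s sampling — sizes at which every oracle is
exhaustively checkable while the full suite runs in seconds.

## Known limitations

* The power model omits drivetrain losses, acceleration transients,
  cadence, and altitude-dependent air density; on real rides the scored
  rider energy inherits those approximations.
* The ability ladder's printed powers embed an effective rider heavier than
  the nominal reference; the package exposes both readings rather than
  silently correcting either.
* Hard grade binning can fragment around bin edges under elevation noise
  (see above).
* The simulator's physiology is deliberately minimal; its parameters are
  user-set, not fitted to any population.
* Scoring trusts the motor-power channel; a miscalibrated battery-current
  sensor biases scores directly.
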