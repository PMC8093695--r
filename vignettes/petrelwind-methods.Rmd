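---
title: "Wind and commuting flight in fulmarine petrels: models and methods"
author: "petrelwind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wind and commuting flight in fulmarine petrels: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

Procellariiform seabirds extract much of their flight power from wind.
For central-place foragers rearing chicks — here three sympatric
fulmarine petrels (cape petrel, Antarctic petrel, southern fulmar) on
the East Antarctic coast — the wind regime is a diurnal katabatic cycle:
easterly flow that peaks in the early morning and slackens around
midday. The package asks, with tested and reusable machinery, how wind
speed and the bird's orientation to the wind shape commuting ground
speed, and whether the birds arrange their headings and their daily
schedule around the wind.

The central covariate is the flight-to-wind offset `ddir_fw`: the folded
absolute angle between the direction of travel and the direction the
wind comes from. 0° is a dead headwind, 90° a crosswind, 180° a full
tailwind. Offsets are cut into headwind [0°, 60°), crosswind [60°, 120°)
and tailwind [120°, 180°] categories; the published category bounds
assign the boundary angles ambiguously, so the half-open partition is
fixed here by convention (the boundaries carry zero probability for
continuous data).

## Pipeline overview

Raw inputs are GPS fixes (15-min target interval), 1-s wet/dry immersion
events, and a gridded 10-m wind field (3-h, ~10-km resolution). The
processing chain is:

1. **Regularisation** — fixes are snapped to the 15-min grid and short
   gaps (default at most 45 min, configurable) are filled along the
   great circle at time-proportional fractions. Longer gaps start a new
   segment. All geodesy is spherical with radius 6371.0 km; at 15-min
   spacing the ellipsoidal correction is far below GPS noise.
2. **Kinematics** — ground speed and flight direction are computed
   between consecutive fixes and assigned to the interval's *end* point,
   which keeps the wind lookup causal; turning angle is the absolute
   bearing change folded to [0°, 180°]. The assignment side is not
   dictated by the study design; end-point assignment is this package's
   choice.
3. **Foraging flag** — a point is flagged as foraging when at least one
   `wet_in` event falls in the half-open 15-min window ending at it.
4. **Movement states** — a four-state expectation–maximisation binary
   clustering of (velocity, turning angle): a quadrant-seeded
   4-component Gaussian-mixture EM, states labelled LL/LH/HL/HH
   (low/high velocity × low/high turn; resting, intensive search,
   travelling, extensive search). This is a self-contained
   re-implementation in the spirit of the published binary-clustering
   algorithm, not a line-by-line port: no pre-binning, no certainty
   annotation, a covariance floor of `1e-6 · trace/2` per component
   against collapse, and delimiter-based labelling (two lowest velocity
   means are "L" velocity; within each velocity pair the lower turn mean
   is "L" turn). The state model is fitted per species by default; the
   grouping is configurable because the original study does not state
   its choice.
5. **Trips and legs** — a foraging trip is a maximal run of points
   beyond the colony-exclusion radius (2 km, doubling as the near-nest
   criterion) that exceeds 10 km from the nest and contains dive data.
   Legs use a distance-fraction rule with f = 0.8: outbound runs through
   the first point at ≥ f·max distance (inclusive), return from the last
   such point (inclusive), middle strictly between; a single spike
   becomes the middle on its own. The original legs followed a
   population-level time/distance procedure that is not restated in
   enough detail to reproduce; the fraction rule is deterministic,
   monotone in f, and configurable.
6. **Wind annotation** — nearest grid node in space, linear
   interpolation in time (a 3-h staircase would alias the diurnal
   analysis), meteorological convention throughout (u eastward, v
   northward, direction = where the wind comes *from*).
7. **Commute filter** — keep outbound/return points with no foraging
   flag, state HL or HH, and distance > 2 km. Deliberately, *no* ground
   speed threshold is applied: slow flight into strong headwind is real
   commuting.

## Statistical layer

*Ground-speed models.* Gaussian linear mixed models with random
intercepts for bird and trip-within-bird, fitted by REML (`lme4`), with
Satterthwaite Type-III term tests (`lmerTest`). When every bird has a
single trip the trip term is aliased with the bird term and is dropped,
reported as a zero component with a singular flag. Marginal effects are
fixed-effect prediction differences, covariates held at sample means
(or stated values). Marginal/conditional R² follow the variance
partition: fixed / (fixed + random + residual), and (fixed + random)
over the same denominator; logit-family models use the standard logistic
residual constant π²/3.

*Fractional logit.* The offset rescaled to [0, 1] is modelled on the
logit scale with quasi-binomial variance by penalised quasi-likelihood
(`MASS::glmmPQL`) keeping the same nested random intercepts. A literal
binomial likelihood on a continuous proportion is improper; the
quasi-likelihood formulation with model-based dispersion serves the same
robustness intent as sandwich errors while retaining explicit random
effects. Exact 0/1 responses are admissible. If the response is
degenerate (no residual variation) the random structure is not
estimable and the model falls back to a quasi-binomial GLM with zero
variance components, flagged singular.

*Diurnal models.* Per bird and local hour (UTC + 7 h, Davis station
time), the proportion of points per class (trip section, or wind
category) is modelled on a cyclic regression-spline basis of hour
(period 24, basis size k = 5 to avoid overfitting) in a weighted
quasi-binomial model with a bird random intercept (`mgcv`). Two
complementary classes carry a single binomial observation per
bird-hour, so the class-by-hour interaction question reduces to the
significance of the cyclic smooth for the reference class; with three or
more classes the departures are ordered-factor difference smooths,
combined by Bonferroni. Deviance comparisons between penalised fits
were rejected during development: with mirrored two-class data the
class-specific model absorbs binomial noise at twice the rate the
degrees-of-freedom accounting expects, inflating the type-I error an
order of magnitude; the smooth-significance tests hold the nominal 5%
size in the package's own 200-replicate null calibration.

*Model simplification.* Backward stepwise elimination drops the
highest-order interaction with the largest Type-III p ≥ 0.05, never a
main effect; when the top interaction is significant the procedure stops
and flags that interpretation should proceed on data subsets (by
species or wind category), which is how the original analysis handled
its significant 4-way interaction.

*Contrasts.* Pairwise comparisons of adjusted means use `emmeans` with
studentized-range (Tukey) adjustment; with two levels this reduces to
the unadjusted t test.

## The synthetic study system

The generator exists so that every downstream stage can be tested by
*recovery*: it plants known states, legs and wind-response coefficients
and the pipeline must find them.

**Wind field.** Speed at time t and cell x is
`clip0[(base + A·cos(2π(t_loc − peak)/24))·exp(−d_off/L) + ε_t]` with an
AR(1) weather disturbance shared across the grid and a von Mises
direction about the prevailing easterly, one draw per 3-h step. Defaults:
base 7.5 m/s, amplitude 2.5 m/s, peak at 04:00 local, direction from
90° with concentration κ = 2.5, offshore e-folding 400 km, weather sd
2.2 m/s with 3-h autocorrelation 0.5, 40 days on a ~10-km grid. These
were fixed once as a plausible coastal katabatic regime with enough
within-trip wind variation to identify wind slopes, and not revisited.

**Agents.** A trip departs the nest with an outbound base heading in the
NW–NNE sector, per-step wrapped-normal heading jitter (sd 50°) so the
realised offsets span [0°, 180°], then drifts slowly eastward through a
foraging middle (dive bouts, and near-stationary resting bouts that give
the clustering a genuine low-velocity/low-turn state), and returns
steering at the nest with an eastward bow that closes the loop clockwise
— the dominant pattern in the study system. During commutes the planted
ground-speed law is

`speed = airspeed + d45·(ddir − 90)/45 + gain·tailcomp + noise`,

with `tailcomp = −w·cos(ddir)`, `gain` the tailwind or headwind gain by
the sign of `tailcomp`, and the direct term vanishing in calm air (the
offset is undefined without wind). The wind entering the law is looked
up exactly where the annotation stage will look it up — at the step's
end time and end position, solved by fixed-point iteration — so with all
noise terms zero the simulate → process → annotate chain reproduces the
law bit-for-bit. On the return leg the meal (drawn uniformly from
species ranges: 3–55 g for cape petrels, 50–250 g for the other two)
raises wing loading; the airspeed scales with the wing-loading ratio to
the 0.25 power and the tailwind gain to the 0.5 power. The full
square-root airspeed scaling suggested by flight mechanics proved to
couple the return-leg intercept to the diurnal wind cycle through
return timing, destabilising the within-category slope recovery; the
milder default keeps the planted section contrast detectable while the
dedicated interaction test plants a stronger one explicitly. Departure
hours are drawn from an early-morning/evening mixture of wrapped
normals; per-bird airspeed intercepts (sd 0.4 m/s) create the nested
random-effect structure.

**Calibration.** The wind-response coefficients shipped in
`species.yml` were calibrated, once, so that running the full pipeline
at the study scale (8 birds × 5 trips per species) recovers the three
published marginal effects per species: the ground-speed change per 45°
tailward offset shift (+3.15 / +1.8 / +1.35 m/s for Antarctic petrel /
cape petrel / southern fulmar), per +5 m/s wind under tailwind (+3.45 /
+2.6 / +0.85 m/s) and under headwind (−4 / −1.35 / −1.2 m/s). The
morphometry (mass, wingspan, wing area — hence wing loading and aspect
ratio) is the colony average for each species and is not a free
parameter.

**What the generator does not emulate.** No gust-soaring mechanics, sea
ice, prey fields or energetics; no spatial weather structure beyond the
offshore decay; no GPS position error; departure timing is calibrated
only qualitatively. Passing recovery tests therefore demonstrates that
the pipeline measures what it claims on data with the assumed
statistical structure — not that the assumed structure is the truth of
the deposited field data.

## Numerical choices and degenerate inputs

- EM stops when the log-likelihood gain drops below 1e-6 (at most 500
  iterations); the trace is retained and asserted non-decreasing within
  1e-8. A constant clustering variable is rejected with advice to use
  fewer states.
- Classification ties break toward the larger mixing weight, then the
  fixed label order LL < LH < HL < HH.
- Leg splitting requires ≥ 3 points; trips bounded by the near-nest
  radius; loop orientation uses the shoelace sign in a local
  equirectangular projection (adequate at trip scale near 69°S), with
  |area| < 1 km² reported as undetermined.
- Wind lookups outside the field's hull or span raise errors naming the
  offending rows rather than extrapolating.
- The full-pipeline survival of planted commuting points is capped by
  the leg rule itself: the commute chunk beyond f·max distance is, by
  construction, assigned to the middle, so overall survival sits near
  1 − (1 − f) of the planted commute, while survival *on the assigned
  commute legs* exceeds 90%. Tests assert both, at those levels.

## Problem sizes

Recovery experiments run at the study scale of 8 birds × 5 trips per
species (roughly 1,700–1,900 commuting points per species); unit and
property tests use a 3 × 3 colony and purpose-built toys; the diurnal
null calibration uses 200 replicates of an 8-bird flat-null design.

## Known limitations

- The movement-state step is a simplified re-implementation; on real
  data the published package's pre-processing could label boundary
  points differently.
- The fractional-logit PQL fit does not supply a true likelihood, so
  likelihood-based comparison across fractional-logit models is not
  offered.
- Term-level F statistics use the Satterthwaite approximation; the
  original study's package used a different denominator-df method, so
  printed F values are not expected to match numerically — effect sizes
  are the comparable quantities.
- NetCDF wind grids are not read directly; supply the equivalent
  long-format CSV.
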