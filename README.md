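# petrelwind

Wind shapes the commuting flight of seabirds that shuttle between a
breeding colony and offshore foraging grounds. `petrelwind` is an R
package for analysing that interplay in GPS-tracked central-place
foragers, built around three Antarctic fulmarine petrels (cape petrel
*Daption capense*, Antarctic petrel *Thalassoica antarctica*, southern
fulmar *Fulmarus glacialoides*) breeding on the East Antarctic coast,
where easterly katabatic winds peak in the early morning and slacken at
midday.

It provides, as a tested pipeline:

- great-circle regularisation of GPS fixes to a 15-min grid and
  kinematic derivation (ground speed, flight direction, turning angle);
- aggregation of 1-s wet/dry immersion events to a binary foraging flag;
- a four-state expectation–maximisation binary clustering of
  (velocity, turning angle) into LL/LH/HL/HH movement states;
- foraging-trip detection (> 10 km from the nest, with dive data),
  outbound/middle/return leg assignment, commute filtering and loop
  orientation;
- spatio-temporal wind annotation and the flight-to-wind offset
  ΔDir_fw ∈ [0°, 180°] (0° headwind, 90° crosswind, 180° tailwind),
  with head/cross/tailwind categories split at 60° and 120°;
- the statistical layer: linear mixed models of ground speed with trip
  nested in bird, marginal effects, marginal/conditional R² (variance
  partition), fractional-logit models of ΔDir_fw, cyclic-spline diurnal
  proportion models, Tukey-adjusted contrasts, backward simplification;
- a synthetic study system — a diurnal katabatic wind field and
  central-place foraging agents with a planted wind-response law — so
  the entire chain is testable by parameter recovery without any data
  download.

The core model is the ground-speed LMM

```
ground_speed ~ wind_speed * ΔDir_fw + (1 | bird / trip)
```

whose marginal effects are reported as the speed change per 45° tailward
shift of ΔDir_fw at mean wind, and per +5 m/s wind within the tailwind
and headwind categories.

## Worked example

Simulate one species' colony at the study scale, run the full chain and
recover its wind response:

```r
library(petrelwind)

species_defaults("antarctic_petrel")
#> <species_params> antarctic_petrel: mass 0.714 kg, wingspan 1.06 m, wing area 0.0957 m^2
#>   wing loading 7.46 kg/m^2, aspect ratio 11.74
#>   airspeed 12.0 m/s, gains tail 0.855 / head 0.985, direct 0.01 m/s per 45 deg

rec <- recover_marginal_effects("antarctic_petrel", n_birds = 8,
                                trips_per_bird = 5, seed = 1)
rec$models$interaction
#> <model_result> gaussian: ground_speed ~ wind_speed * ddir_fw + (1 | bird_id/trip_id)
#>                    estimate     se        df        t      p
#> (Intercept)         12.8026 0.1827   26.5413  70.0698 0.0000
#> wind_speed          -1.2475 0.0223 1498.3359 -55.8207 0.0000
#> ddir_fw             -0.0041 0.0015 1612.7077  -2.7098 0.0068
#> wind_speed:ddir_fw   0.0132 0.0002 1609.3084  56.2706 0.0000
#> variance components:
#> trip_id:bird_id         bird_id        Residual
#>          0.0169          0.1262          1.5494
#> R2 marginal 0.897, conditional 0.906

c(per45 = rec$per45, tail5 = rec$tail5, head5 = rec$head5)
#>     per45     tail5     head5
#>  3.324096  3.489736 -3.867804
```

Reading the output: the positive `wind_speed:ddir_fw` interaction says
stronger wind speeds birds up when it blows from behind and slows them
when it blows from ahead. At mean wind, turning 45° further downwind is
worth +3.3 m/s of ground speed for this Antarctic-petrel-like simulation
(published estimate from the field study: +3.15 m/s); +5 m/s of wind is
worth +3.5 m/s under tailwind (+3.45 published) and −3.9 m/s under
headwind (−4 published). Between-bird and trip-within-bird variance
components and the variance-partition R² are reported with every fit.

Lower-level entry points: `simulate_wind_field()`, `simulate_colony()`,
`process_dataset()`, `annotate_wind()`, `filter_commute()`, `fit_lmm()`,
`fit_diurnal_model()`, and a thin command-line wrapper
(`inst/cli/petrelwind.R`) with subcommands
`simulate | process | annotate | fit | report`.

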