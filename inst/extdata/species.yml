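# Colony-average morphometry for the three study species (body mass kg,
# wingspan m, wing area m^2) and the calibrated wind-response coefficients
# used by the trip simulator.
cape_petrel:
  mean_mass: 0.469
  mass_sd: 0.048
  wingspan: 0.93
  wing_area: 0.0762
  airspeed_base: 10.0
  tailwind_gain: 0.628
  headwind_gain: 0.322
  ddir_slope_per45: 0.14
  meal_mass_range: [0.003, 0.055]
  speed_noise_sd: 1.0
  bird_intercept_sd: 0.4
antarctic_petrel:
  mean_mass: 0.714
  mass_sd: 0.071
  wingspan: 1.06
  wing_area: 0.0957
  airspeed_base: 12.0
  tailwind_gain: 0.855
  headwind_gain: 0.985
  ddir_slope_per45: 0.01
  meal_mass_range: [0.050, 0.250]
  speed_noise_sd: 1.0
  bird_intercept_sd: 0.4
southern_fulmar:
  mean_mass: 0.783
  mass_sd: 0.085
  wingspan: 1.16
  wing_area: 0.1173
  airspeed_base: 10.5
  tailwind_gain: 0.211
  headwind_gain: 0.284
  ddir_slope_per45: 0.55
  meal_mass_range: [0.050, 0.250]
  speed_noise_sd: 1.0
  bird_intercept_sd: 0.4
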