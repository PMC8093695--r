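test_that("degenerate wind spec yields a constant field", {
  spec <- wind_field_spec(diurnal_amplitude = 0, weather_sd = 0,
                          direction_concentration = Inf,
                          offshore_decay_length = 1e12, n_days = 2)
  fld <- simulate_wind_field(spec, seed = 1)
  sp <- sqrt(fld$u^2 + fld$v^2)
  expect_equal(max(sp) - min(sp), 0, tolerance = 1e-6)
  expect_equal(unique(round(uv_to_dir_from(c(fld$u), c(fld$v)), 6)), 90)
  # exactly easterly: u = -speed, v = 0
  expect_equal(c(fld$u), rep(-spec$base_speed, length(fld$u)),
               tolerance = 1e-6)
  expect_equal(max(abs(fld$v)), 0, tolerance = 1e-6)
})

test_that("the diurnal cycle peaks in the early morning", {
  spec <- wind_field_spec(n_days = 15, lat_step = 0.4, lon_step = 1)
  hits <- vapply(1:10, function(s) {
    fld <- simulate_wind_field(spec, seed = s)
    hr <- (as.numeric(fld$time) / 3600 + spec$local_time_offset_h) %% 24
    spd <- sqrt(fld$u^2 + fld$v^2)
    at_peak <- abs(hr - spec$peak_hour) < 1.6
    at_trough <- abs(hr - (spec$peak_hour + 12) %% 24) < 1.6
    mean(spd[at_peak, , ]) > mean(spd[at_trough, , ])
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("with zero noise the commuting speed law is reproduced exactly", {
  sp <- species_params("test", mean_mass = 0.7, mass_sd = 0, wingspan = 1,
                       wing_area = 0.1, airspeed_base = 11,
                       tailwind_gain = 0.8, headwind_gain = 0.9,
                       ddir_slope_per45 = 0.2,
                       meal_mass_range = c(0.1, 0.1),
                       speed_noise_sd = 0, bird_intercept_sd = 0)
  cfg <- study_config()

  # calm air: every commuting step moves at exactly the airspeed
  calm <- uniform_field(u = 0, v = 0)
  set.seed(4)
  tr <- simulate_trip(sp, calm, cfg,
                      depart_time = as.POSIXct("2016-01-11 02:00", tz = "UTC"))
  out <- tr$truth[tr$truth$leg == "outbound", ]
  expect_equal(out$planted_speed, rep(11, nrow(out)), tolerance = 1e-9)
  ret <- tr$truth[tr$truth$leg == "return", ]
  expect_equal(unique(round(ret$planted_speed, 9)),
               round(11 * (0.8 / 0.7)^sp$return_airspeed_exponent, 9))

  # in wind, the planted speed equals the law evaluated at the wind the
  # annotation stage looks up, and the kinematics recover it exactly
  windy <- uniform_field(u = -6, v = 2)
  set.seed(5)
  tr2 <- simulate_trip(sp, windy, cfg,
                       depart_time = as.POSIXct("2016-01-11 02:00", tz = "UTC"))
  proc <- process_dataset(tr2$fixes, tr2$dives, cfg)
  tp <- annotate_wind(proc$trackpoints, windy)
  truth <- tr2$truth[, c("timestamp", "planted_speed", "behavior", "leg")]
  names(truth)[4] <- "leg_true"
  m <- merge(tp, truth, by = "timestamp")
  com <- m[m$behavior == "commute" & m$leg_true == "outbound", ]
  expect_gt(nrow(com), 5)
  expect_equal(com$ground_speed, com$planted_speed, tolerance = 1e-9)
  gain <- ifelse(com$tailwind_comp > 0, sp$tailwind_gain, sp$headwind_gain)
  law <- 11 + sp$ddir_slope_per45 * (com$ddir_fw - 90) / 45 +
    gain * com$tailwind_comp
  expect_equal(com$ground_speed, law, tolerance = 1e-9)
})

test_that("trips loop clockwise and reach foraging distance", {
  ds <- small_colony()
  trips <- split(ds$truth, ds$truth$trip_id)
  expect_equal(length(trips), 9)   # 3 birds x 3 trips, all completed
  loops <- vapply(trips, function(tr) {
    loop_direction(tr$lat, tr$lon, ds$config$nest_lat, ds$config$nest_lon)
  }, character(1))
  expect_gte(mean(loops == "clockwise"), 0.9)
  maxd <- vapply(trips, function(tr) {
    max(haversine_km(tr$lat, tr$lon, ds$config$nest_lat, ds$config$nest_lon))
  }, numeric(1))
  expect_true(all(maxd >= 10))
  # every trip contains dive events, all within its middle section span
  for (tr in trips) {
    dv <- ds$dives[ds$dives$bird_id == tr$bird_id[1] &
                     ds$dives$timestamp >= min(tr$timestamp) &
                     ds$dives$timestamp <= max(tr$timestamp), ]
    expect_gt(nrow(dv), 0)
    mid <- tr[tr$leg == "middle", ]
    expect_true(all(dv$timestamp <= max(mid$timestamp) + 900))
    expect_true(all(dv$timestamp >= min(mid$timestamp) - 900))
  }
  # ground truth covers every emitted fix
  expect_equal(nrow(ds$truth), nrow(ds$fixes))
})

test_that("ground-speed regression on truth labels recovers the planted gain", {
  ds <- small_colony()
  tr <- ds$truth[ds$truth$behavior == "commute" &
                   is.finite(ds$truth$planted_tailwind_comp), ]
  sp <- species_defaults("antarctic_petrel")
  # outbound leg only: single gain regime per sign of the tailwind component
  out <- tr[tr$leg == "outbound", ]
  fit <- stats::lm(planted_speed ~ I(pmax(planted_tailwind_comp, 0)) +
                     I(pmin(planted_tailwind_comp, 0)) +
                     I((planted_ddir - 90) / 45) + bird_id, data = out)
  est <- stats::coef(fit)
  se <- summary(fit)$coefficients[, 2]
  expect_lt(abs(est[2] - sp$tailwind_gain), 2 * se[2])
  expect_lt(abs(est[3] - sp$headwind_gain), 2 * se[3])
})

test_that("simulation is reproducible and writes a complete dataset", {
  f <- uniform_field(u = -4, v = 1, n_t = 65)
  a <- simulate_colony(species_defaults("cape_petrel"), n_birds = 1,
                       trips_per_bird = 1, field = f, seed = 77)
  b <- simulate_colony(species_defaults("cape_petrel"), n_birds = 1,
                       trips_per_bird = 1, field = f, seed = 77)
  expect_identical(a$fixes, b$fixes)
  expect_identical(a$dives, b$dives)
  expect_equal(length(unique(a$truth$trip_id)), 1)

  dir <- tempfile()
  write_dataset(a, dir)
  expect_true(all(file.exists(file.path(
    dir, c("fixes.csv", "dives.csv", "truth.csv", "wind.csv")))))
  fx <- read_fixes(file.path(dir, "fixes.csv"))
  expect_equal(nrow(fx), nrow(a$fixes))
  expect_equal(fx$lat, a$fixes$lat, tolerance = 1e-9)
})
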