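# Synthetic study system: a diurnal katabatic wind field over a coastal
# grid, and central-place foraging agents that commute through it. The
# generator plants known behavioural states, leg labels and wind-response
# coefficients so that every downstream stage can be tested by recovery.

#' Wind-field generator specification
#'
#' Describes a coastal katabatic regime: a diurnal cycle peaking in the
#' early morning with an easterly prevailing direction, decaying offshore,
#' disturbed by an AR(1) "weather" term shared across the grid.
#'
#' @param base_speed Mean wind speed at the coast, m/s.
#' @param diurnal_amplitude Amplitude of the diurnal cosine, m/s.
#' @param peak_hour Local hour of maximum wind.
#' @param prevailing_direction_from Mean direction the wind comes from,
#'   degrees (90 = easterly).
#' @param direction_concentration von Mises concentration of the direction
#'   about the prevailing one; `Inf` gives a constant direction.
#' @param offshore_decay_length e-folding length of the offshore decay, km.
#' @param weather_ar1_rho AR(1) coefficient of the weather disturbance.
#' @param weather_sd Marginal sd of the weather disturbance, m/s.
#' @param time_step_h Field time step, hours.
#' @param n_days Length of the simulated period, days.
#' @param start_time POSIXct origin of the field.
#' @param lat_range,lon_range Grid extents, degrees.
#' @param lat_step,lon_step Grid steps, degrees (10-km-equivalent defaults).
#' @param coast_lat Latitude of the coastline; offshore distance is the
#'   northward distance from it.
#' @param local_time_offset_h Offset used for the diurnal phase.
#' @return A `wind_field_spec` object.
#' @export
wind_field_spec <- function(base_speed = 7.5,
                            diurnal_amplitude = 2.5,
                            peak_hour = 4,
                            prevailing_direction_from = 90,
                            direction_concentration = 2.5,
                            offshore_decay_length = 400,
                            weather_ar1_rho = 0.5,
                            weather_sd = 2.2,
                            time_step_h = 3,
                            n_days = 40,
                            start_time = as.POSIXct("2016-01-11 00:00:00",
                                                    tz = "UTC"),
                            lat_range = c(-69.4, -66.2),
                            lon_range = c(73, 83),
                            lat_step = 0.09,
                            lon_step = 0.25,
                            coast_lat = -69.0,
                            local_time_offset_h = 7) {
  stopifnot(base_speed >= 0, diurnal_amplitude >= 0,
            weather_ar1_rho >= 0, weather_ar1_rho < 1, weather_sd >= 0,
            direction_concentration > 0, offshore_decay_length > 0,
            time_step_h > 0, n_days > 0)
  structure(as.list(environment()), class = "wind_field_spec")
}

# Best & Fisher (1979) rejection sampler for the von Mises distribution
rvonmises <- function(n, mu_deg, kappa) {
  if (!is.finite(kappa)) return(rep(mu_deg %% 360, n))
  if (kappa < 1e-8) return(stats::runif(n, 0, 360))
  mu <- mu_deg * pi / 180
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- stats::runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      c0 <- kappa * (r - f)
      if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
        theta <- mu + sign(u[3] - 0.5) * acos(f)
        out[i] <- (theta * 180 / pi) %% 360
        break
      }
    }
  }
  out
}

#' Simulate a diurnal katabatic wind field
#'
#' Speed at time t and cell x is
#' `clip0[(base + A cos(2 pi (t_local - peak)/24)) exp(-d_off/L) + e_t]`
#' with `e` an AR(1) disturbance shared over the grid; direction is drawn
#' von Mises about the prevailing direction, one draw per time step
#' (spatially coherent weather).
#'
#' @param spec A [wind_field_spec()].
#' @param seed Integer seed.
#' @return A [wind_field()].
#' @export
simulate_wind_field <- function(spec = wind_field_spec(), seed = 1L) {
  set.seed(seed)
  nt <- as.integer(round(spec$n_days * 24 / spec$time_step_h)) + 1L
  time <- spec$start_time + (seq_len(nt) - 1L) * spec$time_step_h * 3600
  lat <- seq(spec$lat_range[1], spec$lat_range[2], by = spec$lat_step)
  lon <- seq(spec$lon_range[1], spec$lon_range[2], by = spec$lon_step)
  t_loc <- (as.numeric(time) / 3600 + spec$local_time_offset_h) %% 24
  diurnal <- spec$base_speed +
    spec$diurnal_amplitude * cos(2 * pi * (t_loc - spec$peak_hour) / 24)
  # AR(1) weather with stationary marginal sd
  eps <- numeric(nt)
  if (spec$weather_sd > 0) {
    innov_sd <- spec$weather_sd * sqrt(1 - spec$weather_ar1_rho^2)
    eps[1] <- stats::rnorm(1, 0, spec$weather_sd)
    for (k in seq_len(nt - 1L)) {
      eps[k + 1L] <- spec$weather_ar1_rho * eps[k] +
        stats::rnorm(1, 0, innov_sd)
    }
  }
  dir_from <- rvonmises(nt, spec$prevailing_direction_from,
                        spec$direction_concentration)
  d_off <- pmax(0, (lat - spec$coast_lat)) * (pi / 180) * EARTH_RADIUS_KM
  decay <- exp(-d_off / spec$offshore_decay_length)
  u <- array(0, c(nt, length(lat), length(lon)))
  v <- u
  for (k in seq_len(nt)) {
    spd <- pmax(0, diurnal[k] * decay + eps[k])     # length(lat)
    uv <- dir_from_to_uv(spd, dir_from[k])
    u[k, , ] <- matrix(uv$u, length(lat), length(lon))
    v[k, , ] <- matrix(uv$v, length(lat), length(lon))
  }
  wind_field(time, lat, lon, u, v)
}

# planted ground-speed law for a commuting step; tg_mult scales the
# tailwind gain on the loaded (return) leg
speed_law <- function(sp, airspeed, wind_speed, ddir, tg_mult = 1) {
  tc <- tailwind_component(wind_speed, ddir)
  gain <- ifelse(tc > 0, sp$tailwind_gain * tg_mult, sp$headwind_gain)
  # the flight-to-wind offset is undefined in calm air
  direct <- ifelse(wind_speed > 0,
                   sp$ddir_slope_per45 * (ddir - 90) / 45, 0)
  airspeed + direct + gain * tc
}

# one commuting step with the wind looked up where the kinematics will
# look it up: at the step's END time and END position (fixed point, since
# the end position depends on the realised speed)
commute_step <- function(sp, field, lat, lon, t_end, heading, airspeed,
                         noise, tg_mult = 1, min_speed = 0.3) {
  pos <- list(lat = lat, lon = lon)
  speed <- airspeed
  for (it in 1:25) {
    w <- wind_sample_at(field, t_end, pos$lat, pos$lon)
    ddir <- delta_dir_fw(heading, w$wind_dir_from)
    new_speed <- max(min_speed,
                     speed_law(sp, airspeed, w$wind_speed, ddir, tg_mult) +
                       noise)
    pos <- destination_point(lat, lon, heading, new_speed * 900 / 1000)
    if (abs(new_speed - speed) < 1e-10) { speed <- new_speed; break }
    speed <- new_speed
  }
  list(lat = pos$lat, lon = pos$lon, speed = speed, ddir = ddir,
       wind_speed = w$wind_speed,
       tailwind_comp = tailwind_component(w$wind_speed, ddir))
}

#' Simulate one foraging trip
#'
#' A central-place foraging agent leaves the nest on an outbound commute
#' with a heading drawn from the NW-NE sector, drifts eastward through a
#' slow, tortuous middle (foraging) section where wet/dry dive events are
#' emitted, and commutes home S-SW, closing a clockwise loop. During
#' commutes the planted ground-speed law responds to the wind field via
#' the tailwind component with asymmetric head/tail gains plus a direct
#' offset term; on the return leg the meal-mass gain raises the wing
#' loading and the airspeed and tailwind gain are scaled by powers of the
#' wing-loading ratio (see [species_params()]).
#'
#' @param sp A [species_params()].
#' @param field A [wind_field()].
#' @param config A [study_config()] (nest, sampling interval).
#' @param depart_time POSIXct departure.
#' @param bird_id,trip_id Identifiers recorded in the output.
#' @param bird_intercept Bird-level airspeed offset, m/s.
#' @param heading_jitter_sd Wrapped-normal heading perturbation per
#'   commuting step, degrees; spreads the realised flight-to-wind offsets
#'   over [0, 180].
#' @return List with data frames `fixes`, `dives` and `truth` (per-fix
#'   behaviour/leg labels, planted speeds and wind covariates).
#' @export
simulate_trip <- function(sp, field, config = study_config(),
                          depart_time, bird_id = "b1", trip_id = "t1",
                          bird_intercept = 0, heading_jitter_sd = 50) {
  dt_s <- config$sampling_interval_min * 60
  nest <- c(config$nest_lat, config$nest_lon)
  if (nest[1] < min(field$lat) || nest[1] > max(field$lat) ||
      nest[2] < min(field$lon) || nest[2] > max(field$lon)) {
    stop("nest outside wind grid")
  }
  meal <- stats::runif(1, sp$meal_mass_range[1], sp$meal_mass_range[2])
  air_out <- sp$airspeed_base + bird_intercept
  wl_ratio <- (sp$mean_mass + meal) / sp$mean_mass   # wing-loading ratio
  air_ret <- sp$airspeed_base * wl_ratio^sp$return_airspeed_exponent +
    bird_intercept
  tg_ret <- wl_ratio^sp$return_tailgain_exponent
  n_out <- sample(20:32, 1)
  n_mid <- sample(12:22, 1)
  out_heading_base <- (stats::runif(1, -60, 20)) %% 360   # NW through NNE

  lat <- nest[1]; lon <- nest[2]
  t <- as.numeric(depart_time)
  rows <- list(
    list(t = t, lat = lat, lon = lon, behavior = "at_nest",
         leg = "pre", speed = NA, heading = NA, ddir = NA,
         wind_speed = NA, tailwind_comp = NA)
  )
  dives <- list()

  emit <- function(t, lat, lon, behavior, leg, step = NULL) {
    rows[[length(rows) + 1L]] <<- list(
      t = t, lat = lat, lon = lon, behavior = behavior, leg = leg,
      speed = if (is.null(step)) NA else step$speed,
      heading = if (is.null(step)) NA else step$heading,
      ddir = if (is.null(step)) NA else step$ddir,
      wind_speed = if (is.null(step)) NA else step$wind_speed,
      tailwind_comp = if (is.null(step)) NA else step$tailwind_comp)
  }

  do_commute_step <- function(lat, lon, t, heading, airspeed, tg_mult = 1) {
    noise <- stats::rnorm(1, 0, sp$speed_noise_sd)
    st <- commute_step(sp, field, lat, lon,
                       as.POSIXct(t + dt_s, origin = "1970-01-01",
                                  tz = "UTC"),
                       heading, airspeed, noise, tg_mult)
    st$heading <- heading
    st
  }

  # keep the agent one step's reach inside the field hull
  safe <- c(min(field$lat) + 0.25, max(field$lat) - 0.25,
            min(field$lon) + 0.7, max(field$lon) - 0.7)
  inside_safe <- function(lat, lon) {
    lat > safe[1] && lat < safe[2] && lon > safe[3] && lon < safe[4]
  }

  # outbound
  for (i in seq_len(n_out)) {
    if (!inside_safe(lat, lon)) break
    heading <- (out_heading_base +
                  stats::rnorm(1, 0, heading_jitter_sd)) %% 360
    st <- do_commute_step(lat, lon, t, heading, air_out)
    lat <- st$lat; lon <- st$lon; t <- t + dt_s
    emit(t, lat, lon, "commute", "outbound", st)
  }
  # middle: slow tortuous eastward drift with dive bouts; dive bouts are
  # often followed by near-stationary resting (low speed, straight drift)
  rest_heading <- 90
  resting <- FALSE
  for (i in seq_len(n_mid)) {
    if (!inside_safe(lat, lon)) {
      heading <- initial_bearing(lat, lon, nest[1], nest[2])
      resting <- FALSE
    } else if (resting) {
      heading <- (rest_heading + stats::rnorm(1, 0, 6)) %% 360
    } else {
      heading <- (90 + stats::rnorm(1, 0, 60)) %% 360
    }
    if (resting) {
      speed <- stats::runif(1, 0.05, 0.4)
      behavior <- "rest"
    } else {
      speed <- stats::runif(1, 0.2, 2.0)
      behavior <- "forage"
      if (stats::runif(1) < 0.75) {
        nb <- sample(1:5, 1)
        starts <- sort(stats::runif(nb, 0, dt_s - 40))
        for (k in seq_len(nb)) {
          dur <- stats::runif(1, 2, 30)
          t_in <- t + starts[k]
          dives[[length(dives) + 1L]] <- data.frame(
            bird_id = bird_id,
            t = c(t_in, min(t_in + dur, t + dt_s - 1)),
            event = c("wet_in", "wet_out"))
        }
      }
    }
    p <- destination_point(lat, lon, heading, speed * dt_s / 1000)
    lat <- p$lat; lon <- p$lon; t <- t + dt_s
    emit(t, lat, lon, behavior, "middle",
         list(speed = speed, heading = heading, ddir = NA,
              wind_speed = NA, tailwind_comp = NA))
    rest_heading <- heading
    # enter a resting bout after foraging, or continue one
    resting <- if (resting) stats::runif(1) < 0.5 else stats::runif(1) < 0.35
  }
  # return: steer toward the nest, bowed east of the direct line (the
  # homing path drifts downwind of the outbound track, closing the loop
  # clockwise); the bow releases on final approach
  for (i in 1:120) {
    d_nest <- haversine_km(lat, lon, nest[1], nest[2])
    brg <- initial_bearing(lat, lon, nest[1], nest[2])
    if (d_nest < 6) {
      # final approach: land at the nest at the next grid time
      t <- t + dt_s
      lat <- nest[1]; lon <- nest[2]
      emit(t, lat, lon, "at_nest", "post")
      break
    }
    bow <- -30 * min(1, d_nest / 30)
    heading <- if (inside_safe(lat, lon)) {
      (brg + bow + stats::rnorm(1, 0, heading_jitter_sd * 0.8)) %% 360
    } else {
      brg
    }
    st <- do_commute_step(lat, lon, t, heading, air_ret, tg_ret)
    lat <- st$lat; lon <- st$lon; t <- t + dt_s
    emit(t, lat, lon, "commute", "return", st)
  }

  truth <- do.call(rbind, lapply(rows, function(r) {
    data.frame(bird_id = bird_id, trip_id = trip_id,
               timestamp = as.POSIXct(r$t, origin = "1970-01-01", tz = "UTC"),
               lat = r$lat, lon = r$lon, behavior = r$behavior, leg = r$leg,
               planted_speed = r$speed, planted_heading = r$heading,
               planted_ddir = r$ddir, planted_wind_speed = r$wind_speed,
               planted_tailwind_comp = r$tailwind_comp,
               meal_mass = meal, stringsAsFactors = FALSE)
  }))
  fixes <- truth[, c("bird_id", "timestamp", "lat", "lon")]
  dv <- if (length(dives)) {
    d <- do.call(rbind, dives)
    data.frame(bird_id = d$bird_id,
               timestamp = as.POSIXct(round(d$t), origin = "1970-01-01",
                                      tz = "UTC"),
               event = d$event, stringsAsFactors = FALSE)
  } else {
    data.frame(bird_id = character(), timestamp = as.POSIXct(character()),
               event = character(), stringsAsFactors = FALSE)
  }
  list(fixes = fixes, dives = dv, truth = truth, meal_mass = meal)
}

#' Simulate a colony of tracked birds
#'
#' Draws per-bird airspeed intercepts (so the nested random-effect
#' structure exists downstream), departure hours from an early-morning /
#' evening mixture of wrapped normals, and chains trips per bird through
#' the wind field.
#'
#' @param species List of [species_params()] (or a single one).
#' @param n_birds Birds per species.
#' @param trips_per_bird Trips per bird.
#' @param field A [wind_field()]; defaults to a fresh simulated field.
#' @param config A [study_config()].
#' @param seed Integer seed.
#' @param depart_hour_mix List with `means`, `sds`, `weights` of the
#'   departure-hour mixture (local hours).
#' @return A `simulated_dataset`: list with `fixes`, `dives`, `truth` data
#'   frames and the `field`.
#' @export
simulate_colony <- function(species, n_birds = 8, trips_per_bird = 5,
                            field = NULL, config = study_config(),
                            seed = 1L,
                            depart_hour_mix = list(means = c(4, 20),
                                                   sds = c(2, 2),
                                                   weights = c(0.6, 0.4))) {
  set.seed(seed)
  if (inherits(species, "species_params")) species <- list(species)
  if (is.null(field)) field <- simulate_wind_field(seed = seed + 1000L)
  t0 <- as.numeric(min(field$time))
  t_max <- as.numeric(max(field$time))
  all_fixes <- list(); all_dives <- list(); all_truth <- list()
  for (sp in species) {
    for (b in seq_len(n_birds)) {
      bird_id <- sprintf("%s_b%02d", sp$name, b)
      bi <- stats::rnorm(1, 0, sp$bird_intercept_sd)
      t_cur <- t0 + stats::runif(1, 0, 12) * 3600
      for (tr in seq_len(trips_per_bird)) {
        comp <- sample(seq_along(depart_hour_mix$weights), 1,
                       prob = depart_hour_mix$weights)
        hr <- (stats::rnorm(1, depart_hour_mix$means[comp],
                            depart_hour_mix$sds[comp])) %% 24
        # next local time at that hour after the current time + 2 h rest
        t_ready <- t_cur + 2 * 3600
        loc <- (t_ready / 3600 + config$local_time_offset_h) %% 24
        wait_h <- (hr - loc) %% 24
        depart <- t_ready + wait_h * 3600
        if (depart + 30 * 3600 > t_max) break   # would outrun the field
        trip <- simulate_trip(
          sp, field, config,
          depart_time = as.POSIXct(depart, origin = "1970-01-01", tz = "UTC"),
          bird_id = bird_id,
          trip_id = sprintf("%s_t%02d", bird_id, tr),
          bird_intercept = bi)
        all_fixes[[length(all_fixes) + 1L]] <- trip$fixes
        all_dives[[length(all_dives) + 1L]] <- trip$dives
        all_truth[[length(all_truth) + 1L]] <- trip$truth
        t_cur <- as.numeric(max(trip$truth$timestamp))
      }
    }
  }
  structure(
    list(fixes = do.call(rbind, all_fixes),
         dives = do.call(rbind, all_dives),
         truth = do.call(rbind, all_truth),
         field = field, config = config),
    class = "simulated_dataset"
  )
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf(
    "<simulated_dataset> %d fixes, %d wet/dry events, %d birds, %d trips\n",
    nrow(x$fixes), nrow(x$dives),
    length(unique(x$fixes$bird_id)), length(unique(x$truth$trip_id))))
  invisible(x)
}

#' Write a simulated dataset to CSV files
#'
#' Writes `fixes.csv`, `dives.csv`, `truth.csv` and `wind.csv` into `dir`.
#'
#' @param dataset A `simulated_dataset`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_table_csv(dataset$fixes, file.path(dir, "fixes.csv"))
  write_table_csv(dataset$dives, file.path(dir, "dives.csv"))
  write_table_csv(dataset$truth, file.path(dir, "truth.csv"))
  write_wind_grid(dataset$field, file.path(dir, "wind.csv"))
  invisible(dir)
}
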