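# Shared fixtures, all built in code.

# uniform wind field: one constant (u, v) everywhere
uniform_field <- function(u = -5, v = 0,
                          t0 = as.POSIXct("2016-01-11 00:00:00", tz = "UTC"),
                          n_t = 9, lat = seq(-69.4, -66.2, by = 0.2),
                          lon = seq(73, 83, by = 0.5)) {
  tt <- t0 + (seq_len(n_t) - 1) * 3 * 3600
  dm <- c(n_t, length(lat), length(lon))
  wind_field(tt, lat, lon, array(u, dm), array(v, dm))
}

# small simulated colony, cached per session so several tests can share it
small_colony <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      f <- simulate_wind_field(wind_field_spec(n_days = 20), seed = 501L)
      cache <<- simulate_colony(species_defaults("antarctic_petrel"),
                                n_birds = 3, trips_per_bird = 3,
                                field = f, seed = 501L)
    }
    cache
  }
})

small_pipeline <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- suppressWarnings(run_pipeline(small_colony()))
    }
    cache
  }
})

# regular on-grid track for one bird heading north at constant speed
regular_track <- function(n = 8, speed_ms = 10,
                          t0 = as.POSIXct("2016-01-12 00:00:00", tz = "UTC")) {
  step_km <- speed_ms * 900 / 1000
  lat <- -68.82 + cumsum(c(0, rep(step_km / (6371 * pi / 180), n - 1)))
  data.frame(bird_id = "b1", timestamp = t0 + (seq_len(n) - 1) * 900,
             lat = lat, lon = rep(77.684, n), stringsAsFactors = FALSE)
}

# four well-separated Gaussian clusters in the velocity/turn quadrants
planted_quadrants <- function(n_per = 150, seed = 9) {
  set.seed(seed)
  mk <- function(mv, mt) cbind(rnorm(n_per, mv, 0.8), rnorm(n_per, mt, 12))
  x <- rbind(mk(2, 25), mk(2, 130), mk(12, 25), mk(12, 130))
  x[, 2] <- pmin(pmax(x[, 2], 0), 180)
  list(velocity = x[, 1], turn = x[, 2],
       truth = rep(c("LL", "LH", "HL", "HH"), each = n_per))
}

# per-bird hourly two-class proportion data with class-A probability p_fun
sim_props <- function(p_fun, n_birds = 8, n_per = 10) {
  d <- expand.grid(bird_id = sprintf("b%02d", seq_len(n_birds)), hour = 0:23)
  kA <- stats::rbinom(nrow(d), n_per, p_fun(d$hour))
  rbind(
    data.frame(bird_id = d$bird_id, hour = d$hour, class = "A",
               proportion = kA / n_per, n = n_per),
    data.frame(bird_id = d$bird_id, hour = d$hour, class = "B",
               proportion = 1 - kA / n_per, n = n_per))
}

sim_props_flat <- function() sim_props(function(h) 0.5)

write_temp_csv <- function(d) {
  path <- tempfile(fileext = ".csv")
  petrelwind:::write_table_csv(d, path)
  path
}
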