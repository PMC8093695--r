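# Great-circle geodesy on a sphere of radius 6371.0 km, track
# regularisation to the sampling grid, and kinematic derivation.

EARTH_RADIUS_KM <- 6371.0

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Great-circle (haversine) distance
#'
#' Spherical distance between two points, radius 6371.0 km. Vectorised.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees.
#' @return Distance in km.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  stopifnot(all(abs(c(lat1, lat2)) <= 90))
  p1 <- deg2rad(lat1); p2 <- deg2rad(lat2)
  dphi <- deg2rad(lat2 - lat1)
  dlam <- deg2rad(lon2 - lon1)
  a <- sin(dphi / 2)^2 + cos(p1) * cos(p2) * sin(dlam / 2)^2
  a <- pmin(1, pmax(0, a))
  2 * EARTH_RADIUS_KM * asin(sqrt(a))
}

#' Initial great-circle bearing
#'
#' Bearing at the first point of the great circle towards the second,
#' clockwise from true north in [0, 360). Vectorised.
#'
#' @inheritParams haversine_km
#' @return Bearing in degrees.
#' @export
initial_bearing <- function(lat1, lon1, lat2, lon2) {
  if (any(lat1 == lat2 & (lon1 - lon2) %% 360 == 0)) {
    stop("initial_bearing undefined for identical endpoints")
  }
  p1 <- deg2rad(lat1); p2 <- deg2rad(lat2)
  dlam <- deg2rad(lon2 - lon1)
  y <- sin(dlam) * cos(p2)
  x <- cos(p1) * sin(p2) - sin(p1) * cos(p2) * cos(dlam)
  (rad2deg(atan2(y, x))) %% 360
}

#' Destination point along a great circle
#'
#' Point reached from (lat, lon) travelling `dist_km` on initial bearing
#' `bearing_deg`.
#'
#' @param lat,lon Start coordinates, degrees.
#' @param bearing_deg Initial bearing, degrees clockwise from north.
#' @param dist_km Distance, km.
#' @return List with `lat`, `lon` in degrees (lon in (-180, 180]).
#' @export
destination_point <- function(lat, lon, bearing_deg, dist_km) {
  d <- dist_km / EARTH_RADIUS_KM
  p1 <- deg2rad(lat); l1 <- deg2rad(lon); th <- deg2rad(bearing_deg)
  p2 <- asin(sin(p1) * cos(d) + cos(p1) * sin(d) * cos(th))
  l2 <- l1 + atan2(sin(th) * sin(d) * cos(p1),
                   cos(d) - sin(p1) * sin(p2))
  lon2 <- (rad2deg(l2) + 180) %% 360 - 180
  lon2[lon2 == -180] <- 180
  list(lat = rad2deg(p2), lon = lon2)
}

# intermediate point at fraction f of the great circle a -> b
gc_intermediate <- function(lat1, lon1, lat2, lon2, f) {
  d <- haversine_km(lat1, lon1, lat2, lon2) / EARTH_RADIUS_KM
  if (d < 1e-12) return(list(lat = lat1, lon = lon1))
  A <- sin((1 - f) * d) / sin(d)
  B <- sin(f * d) / sin(d)
  p1 <- deg2rad(lat1); l1 <- deg2rad(lon1)
  p2 <- deg2rad(lat2); l2 <- deg2rad(lon2)
  x <- A * cos(p1) * cos(l1) + B * cos(p2) * cos(l2)
  y <- A * cos(p1) * sin(l1) + B * cos(p2) * sin(l2)
  z <- A * sin(p1) + B * sin(p2)
  lat <- rad2deg(atan2(z, sqrt(x^2 + y^2)))
  lon <- rad2deg(atan2(y, x))
  lon <- (lon + 180) %% 360 - 180
  if (lon == -180) lon <- 180
  list(lat = lat, lon = lon)
}

#' Regularise a track to the sampling grid
#'
#' Snaps fixes to the exact sampling grid (anchored at the first fix) and
#' fills gaps no longer than `max_interpolation_gap_min` with points on the
#' great circle between the bracketing fixes, at time-proportional
#' fractions. Longer gaps start a new contiguous segment.
#'
#' @param fixes Data frame for one bird with columns `bird_id`, `timestamp`
#'   (POSIXct), `lat`, `lon`, sorted by time.
#' @param config A [study_config()].
#' @return Data frame with columns `bird_id`, `timestamp`, `lat`, `lon`,
#'   `segment` (integer id of a contiguous run) and `interpolated` (logical).
#' @export
interpolate_track <- function(fixes, config = study_config()) {
  stopifnot(nrow(fixes) >= 2)
  step_s <- config$sampling_interval_min * 60
  gap_s <- config$max_interpolation_gap_min * 60
  ts <- as.numeric(fixes$timestamp)
  if (is.unsorted(ts, strictly = TRUE)) {
    o <- order(ts)
    fixes <- fixes[o, , drop = FALSE]
    ts <- ts[o]
  }
  # snap each observed fix to the grid anchored at the first fix
  grid_ts <- ts[1] + round((ts - ts[1]) / step_s) * step_s
  keep <- !duplicated(grid_ts)
  fixes <- fixes[keep, , drop = FALSE]
  grid_ts <- grid_ts[keep]

  out <- vector("list", nrow(fixes))
  seg <- 1L
  res_t <- grid_ts[1]; res_lat <- fixes$lat[1]; res_lon <- fixes$lon[1]
  res_seg <- seg; res_int <- FALSE
  for (i in seq_len(nrow(fixes) - 1L)) {
    dt <- grid_ts[i + 1L] - grid_ts[i]
    if (dt > gap_s) {
      seg <- seg + 1L
    } else if (dt > step_s) {
      nfill <- as.integer(round(dt / step_s)) - 1L
      f <- seq_len(nfill) / (nfill + 1L)
      for (k in seq_len(nfill)) {
        p <- gc_intermediate(fixes$lat[i], fixes$lon[i],
                             fixes$lat[i + 1L], fixes$lon[i + 1L], f[k])
        res_t <- c(res_t, grid_ts[i] + k * step_s)
        res_lat <- c(res_lat, p$lat); res_lon <- c(res_lon, p$lon)
        res_seg <- c(res_seg, seg); res_int <- c(res_int, TRUE)
      }
    }
    res_t <- c(res_t, grid_ts[i + 1L])
    res_lat <- c(res_lat, fixes$lat[i + 1L])
    res_lon <- c(res_lon, fixes$lon[i + 1L])
    res_seg <- c(res_seg, seg); res_int <- c(res_int, FALSE)
  }
  data.frame(
    bird_id = fixes$bird_id[1],
    timestamp = as.POSIXct(res_t, origin = "1970-01-01", tz = "UTC"),
    lat = res_lat, lon = res_lon,
    segment = res_seg, interpolated = res_int,
    stringsAsFactors = FALSE
  )
}

#' Derive kinematics on a regularised track
#'
#' Ground speed and flight direction are computed between consecutive fixes
#' of the same contiguous segment and assigned to the interval's end point;
#' the turning angle at point i is the absolute change of bearing between
#' the two intervals ending at i, folded to [0, 180]. The first point of a
#' segment carries `NA` speed/direction, the first two carry `NA` turning
#' angle; those rows are excluded from downstream model data.
#'
#' @param track Output of [interpolate_track()] (one bird).
#' @param nest_lat,nest_lon Nest coordinates, degrees.
#' @return The input with columns `ground_speed` (m/s), `flight_direction`
#'   (degrees [0, 360)), `turning_angle` (degrees [0, 180]) and
#'   `dist_from_nest` (km) appended.
#' @export
compute_kinematics <- function(track, nest_lat, nest_lon) {
  n <- nrow(track)
  gs <- rep(NA_real_, n); fd <- rep(NA_real_, n); ta <- rep(NA_real_, n)
  if (n >= 2) {
    i <- 2:n
    same_seg <- track$segment[i] == track$segment[i - 1L]
    dt <- as.numeric(track$timestamp[i]) - as.numeric(track$timestamp[i - 1L])
    d_km <- haversine_km(track$lat[i - 1L], track$lon[i - 1L],
                         track$lat[i], track$lon[i])
    gs[i] <- ifelse(same_seg, d_km * 1000 / dt, NA_real_)
    mv <- which(same_seg & d_km > 1e-9)
    if (length(mv)) {
      fd[mv + 1L] <- initial_bearing(track$lat[mv], track$lon[mv],
                                     track$lat[mv + 1L], track$lon[mv + 1L])
    }
  }
  if (n >= 3) {
    for (j in 3:n) {
      if (!is.na(fd[j]) && !is.na(fd[j - 1L]) &&
          track$segment[j] == track$segment[j - 2L]) {
        ta[j] <- fold180(fd[j] - fd[j - 1L])
      }
    }
  }
  track$ground_speed <- gs
  track$flight_direction <- fd
  track$turning_angle <- ta
  track$dist_from_nest <- haversine_km(track$lat, track$lon,
                                       nest_lat, nest_lon)
  track
}

# fold an angular difference to [0, 180]
fold180 <- function(x) {
  d <- abs(x) %% 360
  pmin(d, 360 - d)
}

#' Solar elevation angle
#'
#' Low-precision solar-position approximation (fractional-year Fourier
#' expansions for declination and the equation of time, as in the NOAA
#' solar calculator); accurate to a fraction of a degree, ample for
#' day/twilight classification.
#'
#' @param lat,lon Position in degrees.
#' @param timestamp POSIXct (UTC).
#' @return Elevation above the horizon in degrees.
#' @export
solar_elevation <- function(lat, lon, timestamp) {
  t <- as.POSIXlt(timestamp, tz = "UTC")
  doy <- t$yday + 1
  hour_utc <- t$hour + t$min / 60 + t$sec / 3600
  # fractional year (radians)
  g <- 2 * pi / 365 * (doy - 1 + (hour_utc - 12) / 24)
  # equation of time (minutes) and declination (radians), NOAA expansion
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
                        0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  tst <- hour_utc * 60 + eqtime + 4 * lon          # true solar time, minutes
  ha <- deg2rad(tst / 4 - 180)                     # hour angle
  phi <- deg2rad(lat)
  cos_zen <- sin(phi) * sin(decl) + cos(phi) * cos(decl) * cos(ha)
  cos_zen <- pmin(1, pmax(-1, cos_zen))
  90 - rad2deg(acos(cos_zen))
}

#' Classify light conditions from solar elevation
#'
#' `day` above 0 degrees, `nautical_twilight` in (-12, 0], `dark` at or
#' below -12 degrees.
#'
#' @param elevation_deg Solar elevation in degrees.
#' @return Character vector.
#' @export
light_phase <- function(elevation_deg) {
  ifelse(elevation_deg > 0, "day",
         ifelse(elevation_deg > -12, "nautical_twilight", "dark"))
}
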