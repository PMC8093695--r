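# Gridded wind fields, spatio-temporal lookup for track points, the
# flight-to-wind angular offset and its head/cross/tailwind categories.

#' Construct a wind field
#'
#' A regular (time, lat, lon) grid of 10-m wind components in the
#' meteorological convention: `u` eastward, `v` northward (m/s); reported
#' wind direction is the direction the wind comes FROM.
#'
#' @param time POSIXct axis (strictly increasing).
#' @param lat,lon Numeric axes (strictly monotone).
#' @param u,v Arrays of dim `c(length(time), length(lat), length(lon))`.
#' @return A `wind_field` object.
#' @export
wind_field <- function(time, lat, lon, u, v) {
  stopifnot(
    inherits(time, "POSIXct"),
    !is.unsorted(as.numeric(time), strictly = TRUE)
  )
  for (ax in list(lat, lon)) {
    d <- diff(ax)
    if (length(d) && !(all(d > 0) || all(d < 0))) {
      stop("wind_field axes must be strictly monotone")
    }
  }
  dm <- c(length(time), length(lat), length(lon))
  stopifnot(identical(dim(u), dm), identical(dim(v), dm))
  nan_count <- sum(!is.finite(u)) + sum(!is.finite(v))
  if (nan_count > 0) {
    message(nan_count, " non-finite wind cells in field")
  }
  structure(
    list(time = time, lat = lat, lon = lon, u = u, v = v,
         nan_count = nan_count),
    class = "wind_field"
  )
}

#' @export
print.wind_field <- function(x, ...) {
  cat(sprintf(
    "<wind_field> %d times x %d lat x %d lon; %s .. %s; %d non-finite cells\n",
    length(x$time), length(x$lat), length(x$lon),
    format(min(x$time)), format(max(x$time)), x$nan_count))
  invisible(x)
}

#' Read a wind grid from long-format CSV
#'
#' Expects columns `time` (ISO-8601 UTC), `lat`, `lon`, `u`, `v` covering a
#' full regular grid.
#'
#' @param path CSV path.
#' @return A [wind_field()].
#' @export
read_wind_grid <- function(path) {
  if (grepl("\\.nc$", path, ignore.case = TRUE)) {
    stop("NetCDF wind grids are not supported by this build; ",
         "supply the equivalent long-format CSV (time, lat, lon, u, v)")
  }
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time", "lat", "lon", "u", "v")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("wind grid missing column(s): ",
                         paste(miss, collapse = ", "))
  tt <- parse_timestamp(d$time)
  time <- sort(unique(tt))
  lat <- sort(unique(d$lat))
  lon <- sort(unique(d$lon))
  if (nrow(d) != length(time) * length(lat) * length(lon)) {
    stop("wind grid is not a complete time x lat x lon grid")
  }
  it <- match(as.numeric(tt), as.numeric(time))
  ia <- match(d$lat, lat)
  io <- match(d$lon, lon)
  u <- array(NA_real_, c(length(time), length(lat), length(lon)))
  v <- u
  idx <- cbind(it, ia, io)
  u[idx] <- d$u
  v[idx] <- d$v
  wind_field(time, lat, lon, u, v)
}

#' Write a wind field as long-format CSV
#'
#' @param field A [wind_field()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_wind_grid <- function(field, path) {
  g <- expand.grid(ti = seq_along(field$time),
                   ai = seq_along(field$lat),
                   oi = seq_along(field$lon))
  d <- data.frame(
    time = format(field$time[g$ti], "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    lat = field$lat[g$ai],
    lon = field$lon[g$oi],
    u = field$u[cbind(g$ti, g$ai, g$oi)],
    v = field$v[cbind(g$ti, g$ai, g$oi)]
  )
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Sample a wind field at points
#'
#' Nearest grid node in space, linear interpolation in time between the
#' bracketing field times (component-wise on u/v).
#'
#' @param field A [wind_field()].
#' @param timestamp POSIXct vector.
#' @param lat,lon Position vectors, degrees.
#' @return Data frame with `u`, `v`, `wind_speed` (m/s) and
#'   `wind_dir_from` (degrees [0, 360)).
#' @export
wind_sample_at <- function(field, timestamp, lat, lon) {
  tnum <- as.numeric(timestamp)
  ft <- as.numeric(field$time)
  if (any(tnum < ft[1] - 1e-6) || any(tnum > ft[length(ft)] + 1e-6)) {
    bad <- which(tnum < ft[1] | tnum > ft[length(ft)])
    stop("point(s) outside wind field time span: rows ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  rng_lat <- range(field$lat); rng_lon <- range(field$lon)
  out_sp <- lat < rng_lat[1] | lat > rng_lat[2] |
    lon < rng_lon[1] | lon > rng_lon[2]
  if (any(out_sp)) {
    stop("point(s) outside wind field spatial hull: rows ",
         paste(utils::head(which(out_sp), 5), collapse = ", "))
  }
  ia <- nearest_index(field$lat, lat)
  io <- nearest_index(field$lon, lon)
  i0 <- findInterval(tnum, ft, rightmost.closed = TRUE)
  i0 <- pmin(pmax(i0, 1L), length(ft) - 1L)
  if (length(ft) == 1L) {
    i0 <- rep(1L, length(tnum)); frac <- rep(0, length(tnum))
    i1 <- i0
  } else {
    i1 <- i0 + 1L
    frac <- (tnum - ft[i0]) / (ft[i1] - ft[i0])
    frac <- pmin(1, pmax(0, frac))
  }
  u <- (1 - frac) * field$u[cbind(i0, ia, io)] +
    frac * field$u[cbind(i1, ia, io)]
  v <- (1 - frac) * field$v[cbind(i0, ia, io)] +
    frac * field$v[cbind(i1, ia, io)]
  data.frame(u = u, v = v,
             wind_speed = sqrt(u^2 + v^2),
             wind_dir_from = uv_to_dir_from(u, v))
}

nearest_index <- function(axis, x) {
  vapply(x, function(xi) which.min(abs(axis - xi)), integer(1))
}

#' Convert wind components to speed/direction and back
#'
#' Meteorological convention: the direction is where the wind blows FROM,
#' so `u = -speed * sin(dir)`, `v = -speed * cos(dir)`.
#'
#' @param u,v Wind components, m/s.
#' @return `uv_to_dir_from`: direction in degrees [0, 360).
#' @export
uv_to_dir_from <- function(u, v) {
  (rad2deg(atan2(-u, -v))) %% 360
}

#' @rdname uv_to_dir_from
#' @param speed Wind speed, m/s.
#' @param dir_from Direction the wind comes from, degrees.
#' @return `dir_from_to_uv`: list with components `u` and `v`.
#' @export
dir_from_to_uv <- function(speed, dir_from) {
  list(u = -speed * sin(deg2rad(dir_from)),
       v = -speed * cos(deg2rad(dir_from)))
}

#' Flight-to-wind angular offset
#'
#' Folded absolute angle between the flight direction (direction of
#' travel) and the wind direction (direction the wind comes from): 0 means
#' maximum headwind, 90 crosswind, 180 maximum tailwind.
#'
#' @param flight_direction Degrees.
#' @param wind_dir_from Degrees.
#' @return Offset in degrees [0, 180].
#' @export
delta_dir_fw <- function(flight_direction, wind_dir_from) {
  stopifnot(all(is.finite(flight_direction)), all(is.finite(wind_dir_from)))
  fold180(flight_direction - wind_dir_from)
}

#' Head/cross/tailwind category
#'
#' Splits the flight-to-wind offset at the configured bounds (default 60
#' and 120 degrees) into `headwind` [0, 60), `crosswind` [60, 120) and
#' `tailwind` [120, 180].
#'
#' @param ddir Offset in degrees [0, 180].
#' @param bounds Two category bounds in degrees.
#' @return Factor with levels headwind, crosswind, tailwind.
#' @export
wind_category <- function(ddir, bounds = c(60, 120)) {
  if (any(ddir < 0 | ddir > 180, na.rm = TRUE)) {
    stop("ddir outside [0, 180]")
  }
  cut(ddir, breaks = c(-Inf, bounds, Inf), right = FALSE,
      labels = c("headwind", "crosswind", "tailwind"))
}

#' Tailwind component of the wind
#'
#' Projection of the wind vector onto the flight direction:
#' `-wind_speed * cos(ddir)`; positive values assist the bird.
#'
#' @param wind_speed m/s, non-negative.
#' @param ddir Flight-to-wind offset, degrees.
#' @return Component in m/s.
#' @export
tailwind_component <- function(wind_speed, ddir) {
  stopifnot(all(wind_speed >= 0, na.rm = TRUE))
  -wind_speed * cos(deg2rad(ddir))
}

#' Annotate track points with wind
#'
#' Looks up the wind field at each point (nearest node in space, linear in
#' time) and derives the flight-to-wind offset, wind category and tailwind
#' component where a flight direction is defined.
#'
#' @param trackpoints Data frame with `timestamp`, `lat`, `lon` and
#'   (optionally NA) `flight_direction`.
#' @param field A [wind_field()].
#' @param bounds Wind-category bounds, degrees.
#' @return `trackpoints` with `u`, `v`, `wind_speed`, `wind_dir_from`,
#'   `ddir_fw`, `wind_category`, `tailwind_comp` appended.
#' @export
annotate_wind <- function(trackpoints, field, bounds = c(60, 120)) {
  ws <- wind_sample_at(field, trackpoints$timestamp,
                       trackpoints$lat, trackpoints$lon)
  trackpoints$u <- ws$u
  trackpoints$v <- ws$v
  trackpoints$wind_speed <- ws$wind_speed
  trackpoints$wind_dir_from <- ws$wind_dir_from
  dd <- rep(NA_real_, nrow(trackpoints))
  ok <- is.finite(trackpoints$flight_direction)
  dd[ok] <- delta_dir_fw(trackpoints$flight_direction[ok],
                         ws$wind_dir_from[ok])
  trackpoints$ddir_fw <- dd
  trackpoints$wind_category <- wind_category(dd, bounds)
  trackpoints$tailwind_comp <- ifelse(ok,
                                      tailwind_component(ws$wind_speed, dd),
                                      NA_real_)
  trackpoints
}

#' Binned direction histogram
#'
#' Counts of angles in half-open bins `[k*w, (k+1)*w)` covering [0, 360);
#' inputs are reduced modulo 360 first.
#'
#' @param angles Degrees.
#' @param bin_width Bin width; must divide 360.
#' @return Data frame with `bin_start`, `bin_end`, `count`.
#' @export
direction_histogram <- function(angles, bin_width = 10) {
  if (360 %% bin_width != 0) stop("bin_width must divide 360")
  a <- angles %% 360
  nb <- 360 %/% bin_width
  bin <- floor(a / bin_width)
  counts <- tabulate(bin + 1L, nbins = nb)
  data.frame(bin_start = (0:(nb - 1)) * bin_width,
             bin_end = (1:nb) * bin_width,
             count = counts)
}
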