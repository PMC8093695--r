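# Foraging-trip detection, outbound/middle/return leg assignment, commute
# filtering, loop orientation and per-trip summaries.

#' Detect foraging trips
#'
#' A trip is a maximal run of consecutive points (within a bird) farther
#' from the nest than the colony-exclusion radius, bounded by near-nest
#' points; it is retained only if it exceeds the trip distance threshold
#' AND contains at least one foraging (dive) flag.
#'
#' @param trackpoints Data frame with `bird_id`, `timestamp`,
#'   `dist_from_nest` and `foraging` (0/1).
#' @param config A [study_config()].
#' @return `trackpoints` with a `trip_id` column (`NA` off-trip), plus an
#'   attribute `trips`: one row per retained trip.
#' @export
detect_trips <- function(trackpoints, config = study_config()) {
  stopifnot(all(c("dist_from_nest", "foraging") %in% names(trackpoints)))
  trackpoints$trip_id <- NA_character_
  trips <- list()
  for (b in unique(trackpoints$bird_id)) {
    idx <- which(trackpoints$bird_id == b)
    away <- trackpoints$dist_from_nest[idx] > config$colony_exclusion_radius_km
    r <- rle(away)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    tn <- 0L
    for (k in seq_along(r$values)) {
      if (!r$values[k]) next
      run <- idx[starts[k]:ends[k]]
      maxd <- max(trackpoints$dist_from_nest[run])
      has_dive <- any(trackpoints$foraging[run] == 1)
      if (maxd > config$trip_distance_threshold_km && has_dive) {
        tn <- tn + 1L
        tid <- sprintf("%s_trip%02d", b, tn)
        trackpoints$trip_id[run] <- tid
        trips[[tid]] <- data.frame(
          trip_id = tid, bird_id = b,
          start = trackpoints$timestamp[run[1]],
          end = trackpoints$timestamp[run[length(run)]],
          n_points = length(run),
          max_dist_from_nest = maxd,
          stringsAsFactors = FALSE)
      }
    }
  }
  attr(trackpoints, "trips") <- if (length(trips)) {
    do.call(rbind, trips)
  } else {
    data.frame(trip_id = character(), bird_id = character(),
               n_points = integer(), max_dist_from_nest = numeric())
  }
  trackpoints
}

#' Split a trip into outbound, middle and return legs
#'
#' With f the leg fraction threshold (default 0.8): outbound runs from the
#' trip start through (inclusive) the first point at distance >= f * max
#' distance; return runs from (inclusive) the last such point to the trip
#' end; everything strictly between is middle. If outbound and return
#' would overlap (a single distance spike), the peak point alone is the
#' middle and the legs are the strict prefix and suffix.
#'
#' @param dist_from_nest Distances of the trip's points, km, in time order.
#' @param f Leg fraction threshold in (0, 1).
#' @return Character vector of labels `outbound`/`middle`/`return`.
#' @export
split_legs <- function(dist_from_nest, f = 0.8) {
  n <- length(dist_from_nest)
  if (n < 3) stop("trip must have at least 3 points to split into legs")
  stopifnot(f > 0, f < 1)
  thr <- f * max(dist_from_nest)
  at_peak <- which(dist_from_nest >= thr)
  first <- at_peak[1]; last <- at_peak[length(at_peak)]
  leg <- rep("middle", n)
  if (first == last) {              # single spike: peak alone is middle
    if (first > 1) leg[1:(first - 1L)] <- "outbound"
    if (last < n) leg[(last + 1L):n] <- "return"
  } else {
    leg[1:first] <- "outbound"
    leg[last:n] <- "return"
  }
  leg
}

#' Filter to commuting points
#'
#' Retains points on outbound/return legs with no foraging activity,
#' movement state HL or HH, and distance from the nest beyond the colony
#' exclusion radius. No ground-speed threshold is applied.
#'
#' @param trackpoints Data frame with `leg`, `foraging`, `state`,
#'   `dist_from_nest`.
#' @param config A [study_config()].
#' @return The commuting subset of `trackpoints`.
#' @export
filter_commute <- function(trackpoints, config = study_config()) {
  keep <- trackpoints$leg %in% c("outbound", "return") &
    trackpoints$foraging == 0 &
    trackpoints$state %in% c("HL", "HH") &
    trackpoints$dist_from_nest > config$colony_exclusion_radius_km
  keep[is.na(keep)] <- FALSE
  out <- trackpoints[keep, , drop = FALSE]
  if (nrow(out) == 0) warning("no commuting points retained")
  out
}

#' Loop orientation of a trip
#'
#' Sign of the shoelace area of the trip polygon closed at the nest, in a
#' local equirectangular projection (x = lon * cos(mean lat), y = lat).
#' Negative area in this north-up frame means a clockwise loop.
#'
#' @param lat,lon Trip coordinates in time order, degrees.
#' @param nest_lat,nest_lon Nest coordinates, degrees.
#' @param tol_km2 Area below which the orientation is `undetermined`.
#' @return One of "clockwise", "counterclockwise", "undetermined".
#' @export
loop_direction <- function(lat, lon, nest_lat, nest_lon, tol_km2 = 1) {
  stopifnot(length(lat) >= 4)
  la <- c(nest_lat, lat, nest_lat)
  lo <- c(nest_lon, lon, nest_lon)
  mlat <- mean(la)
  km_deg <- pi / 180 * EARTH_RADIUS_KM
  x <- lo * cos(mlat * pi / 180) * km_deg
  y <- la * km_deg
  n <- length(x)
  area <- sum(x[-n] * y[-1] - x[-1] * y[-n]) / 2
  if (abs(area) < tol_km2) return("undetermined")
  if (area < 0) "clockwise" else "counterclockwise"
}

#' Per-trip summary
#'
#' One row per trip: maximum distance, duration, loop orientation and the
#' mean flight-to-wind offset over commuting outbound points (NA, with a
#' message, if the trip has none).
#'
#' @param trackpoints Fully annotated points of one trip (columns `leg`,
#'   `foraging`, `state`, `ddir_fw`, `dist_from_nest`, `lat`, `lon`,
#'   `timestamp`).
#' @param config A [study_config()].
#' @return One-row data frame.
#' @export
trip_summary <- function(trackpoints, config = study_config()) {
  stopifnot(nrow(trackpoints) >= 1)
  out_pts <- trackpoints$leg == "outbound" & trackpoints$foraging == 0 &
    trackpoints$state %in% c("HL", "HH") & !is.na(trackpoints$ddir_fw)
  out_pts[is.na(out_pts)] <- FALSE
  mean_ddir <- if (any(out_pts)) {
    mean(trackpoints$ddir_fw[out_pts])
  } else {
    message("trip ", trackpoints$trip_id[1],
            ": no commuting outbound points; outbound ddir is NA")
    NA_real_
  }
  loop <- if (nrow(trackpoints) >= 4) {
    loop_direction(trackpoints$lat, trackpoints$lon,
                   config$nest_lat, config$nest_lon)
  } else {
    "undetermined"
  }
  data.frame(
    trip_id = trackpoints$trip_id[1],
    bird_id = trackpoints$bird_id[1],
    max_dist_from_nest = max(trackpoints$dist_from_nest),
    duration_h = as.numeric(max(trackpoints$timestamp) -
                              min(trackpoints$timestamp), units = "hours"),
    mean_outbound_ddir_fw = mean_ddir,
    loop_sign = loop,
    stringsAsFactors = FALSE
  )
}
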