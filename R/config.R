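#' Study configuration
#'
#' Collects the thresholds and conventions used throughout the pipeline:
#' colony geometry, trip and leg thresholds, the GPS sampling interval,
#' wind-category bounds and the local-time offset used to derive hour of day.
#'
#' @param nest_lat,nest_lon Colony/nest coordinates in decimal degrees.
#'   Per-bird nests may be supplied downstream; these are the defaults.
#' @param colony_exclusion_radius_km Positions closer to the nest than this
#'   are dropped from commute analyses and used as the near-nest criterion
#'   when delimiting trips (km).
#' @param trip_distance_threshold_km Minimum maximum-distance from the nest
#'   for an excursion to count as a foraging trip (km).
#' @param sampling_interval_min Target GPS sampling interval (minutes).
#' @param max_interpolation_gap_min Gaps up to this length are filled by
#'   great-circle interpolation; longer gaps start a new track segment.
#' @param leg_fraction_threshold Fraction of the trip's maximum distance
#'   used to delimit outbound/middle/return legs (0 < f < 1).
#' @param wind_category_bounds Two angles (degrees) splitting the
#'   flight-to-wind offset into headwind / crosswind / tailwind.
#' @param local_time_offset_h Hours added to UTC to obtain local time
#'   (default +7, Davis station time).
#' @param random_seed Integer seed recorded in run manifests.
#'
#' @return An object of class `study_config` (a named list).
#' @export
study_config <- function(nest_lat = -68.820,
                         nest_lon = 77.684,
                         colony_exclusion_radius_km = 2,
                         trip_distance_threshold_km = 10,
                         sampling_interval_min = 15,
                         max_interpolation_gap_min = 45,
                         leg_fraction_threshold = 0.8,
                         wind_category_bounds = c(60, 120),
                         local_time_offset_h = 7,
                         random_seed = 1L) {
  stopifnot(
    is.numeric(nest_lat), nest_lat >= -90, nest_lat <= 90,
    is.numeric(nest_lon), nest_lon > -180, nest_lon <= 180,
    colony_exclusion_radius_km > 0,
    trip_distance_threshold_km > 0,
    sampling_interval_min > 0,
    max_interpolation_gap_min >= sampling_interval_min,
    leg_fraction_threshold > 0, leg_fraction_threshold < 1,
    length(wind_category_bounds) == 2,
    wind_category_bounds[1] > 0,
    wind_category_bounds[1] < wind_category_bounds[2],
    wind_category_bounds[2] < 180
  )
  structure(
    list(
      nest_lat = nest_lat,
      nest_lon = nest_lon,
      colony_exclusion_radius_km = colony_exclusion_radius_km,
      trip_distance_threshold_km = trip_distance_threshold_km,
      sampling_interval_min = sampling_interval_min,
      max_interpolation_gap_min = max_interpolation_gap_min,
      leg_fraction_threshold = leg_fraction_threshold,
      wind_category_bounds = wind_category_bounds,
      local_time_offset_h = local_time_offset_h,
      random_seed = as.integer(random_seed)
    ),
    class = "study_config"
  )
}

#' Read a study configuration from a YAML file
#'
#' Keys match the arguments of [study_config()]; missing keys fall back to
#' the defaults.
#'
#' @param path Path to a YAML key/value file.
#' @return A `study_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(study_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    warning("ignoring unknown config keys: ", paste(unknown, collapse = ", "))
    vals <- vals[intersect(names(vals), known)]
  }
  do.call(study_config, vals)
}

#' @export
print.study_config <- function(x, ...) {
  cat("<study_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-28s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}

# local (UTC + offset) clock hour in [0, 24) as a real number
local_hour <- function(timestamp, config) {
  t_loc <- as.numeric(timestamp) / 3600 + config$local_time_offset_h
  t_loc %% 24
}
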