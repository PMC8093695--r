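# Species morphometry and simulator response coefficients. Morphometric
# defaults are colony averages for the three study species (cape petrel,
# Antarctic petrel, southern fulmar); wind-response coefficients are the
# packaged calibration of the synthetic-data generator.

#' Species parameters
#'
#' Morphometry plus the response coefficients the trip simulator uses.
#' Wing loading (kg/m^2) and aspect ratio are derived, not stored.
#'
#' @param name Species label.
#' @param mean_mass,mass_sd Body mass, kg.
#' @param wingspan Wingspan, m.
#' @param wing_area Total wing area, m^2.
#' @param airspeed_base Still-air commuting ground speed, m/s.
#' @param tailwind_gain Ground-speed gain per m/s of (positive) tailwind
#'   component, unitless.
#' @param headwind_gain Ground-speed loss per m/s of (negative) tailwind
#'   component, unitless.
#' @param ddir_slope_per45 Direct (wind-speed-independent) ground-speed
#'   change per 45 degrees of flight-to-wind offset, m/s.
#' @param meal_mass_range Two kg values; per-trip meal mass is drawn
#'   uniformly from this interval.
#' @param speed_noise_sd Residual ground-speed noise, m/s.
#' @param bird_intercept_sd Between-bird airspeed intercept sd, m/s.
#' @param return_airspeed_exponent Exponent of the wing-loading ratio
#'   applied to the airspeed on the return (loaded) leg.
#' @param return_tailgain_exponent Exponent of the wing-loading ratio
#'   applied to the tailwind gain on the return leg; plants a
#'   section-dependent wind response under tailwind.
#' @return A `species_params` object.
#' @export
species_params <- function(name, mean_mass, mass_sd, wingspan, wing_area,
                           airspeed_base, tailwind_gain, headwind_gain,
                           ddir_slope_per45, meal_mass_range,
                           speed_noise_sd = 1.0, bird_intercept_sd = 0.4,
                           return_airspeed_exponent = 0.25,
                           return_tailgain_exponent = 0.5) {
  stopifnot(mean_mass > 0, wing_area > 0, wingspan > 0,
            airspeed_base > 0, length(meal_mass_range) == 2,
            meal_mass_range[1] <= meal_mass_range[2],
            speed_noise_sd >= 0, bird_intercept_sd >= 0)
  structure(
    list(name = name, mean_mass = mean_mass, mass_sd = mass_sd,
         wingspan = wingspan, wing_area = wing_area,
         airspeed_base = airspeed_base,
         tailwind_gain = tailwind_gain, headwind_gain = headwind_gain,
         ddir_slope_per45 = ddir_slope_per45,
         meal_mass_range = meal_mass_range,
         speed_noise_sd = speed_noise_sd,
         bird_intercept_sd = bird_intercept_sd,
         return_airspeed_exponent = return_airspeed_exponent,
         return_tailgain_exponent = return_tailgain_exponent),
    class = "species_params"
  )
}

#' @rdname species_params
#' @param sp A `species_params`.
#' @export
wing_loading <- function(sp) sp$mean_mass / sp$wing_area

#' @rdname species_params
#' @export
aspect_ratio <- function(sp) sp$wingspan^2 / sp$wing_area

#' @export
print.species_params <- function(x, ...) {
  cat(sprintf(
    "<species_params> %s: mass %.3f kg, wingspan %.2f m, wing area %.4f m^2\n",
    x$name, x$mean_mass, x$wingspan, x$wing_area))
  cat(sprintf("  wing loading %.2f kg/m^2, aspect ratio %.2f\n",
              wing_loading(x), aspect_ratio(x)))
  cat(sprintf("  airspeed %.1f m/s, gains tail %.3f / head %.3f, direct %.2f m/s per 45 deg\n",
              x$airspeed_base, x$tailwind_gain, x$headwind_gain,
              x$ddir_slope_per45))
  invisible(x)
}

#' Packaged species defaults
#'
#' Loads the shipped `species.yml` with colony-average morphometry and the
#' calibrated simulator response coefficients for the three study species.
#'
#' @param name Optional species name (`cape_petrel`, `antarctic_petrel`,
#'   `southern_fulmar`); omit for the full named list.
#' @return A `species_params` or a named list of them.
#' @export
species_defaults <- function(name = NULL) {
  path <- system.file("extdata", "species.yml", package = "petrelwind")
  if (path == "") path <- file.path("inst", "extdata", "species.yml")
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(nm) {
    vals <- raw[[nm]]
    vals$name <- nm
    vals$meal_mass_range <- unlist(vals$meal_mass_range)
    do.call(species_params, vals)
  })
  names(out) <- names(raw)
  if (is.null(name)) return(out)
  if (!name %in% names(out)) {
    stop("unknown species '", name, "'; available: ",
         paste(names(out), collapse = ", "))
  }
  out[[name]]
}
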