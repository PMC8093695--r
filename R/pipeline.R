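# Orchestration of the full processing chain: regularisation ->
# kinematics -> dive aggregation -> movement-state clustering -> trip and
# leg segmentation -> wind annotation -> commute filter.

#' Process raw fixes and dive events into annotated track points
#'
#' Runs, per bird: great-circle regularisation to the sampling grid and
#' kinematic derivation; then dive aggregation to the binary foraging
#' flag, movement-state clustering (fitted per species when a species map
#' is given, else globally), trip detection and leg assignment.
#'
#' @param fixes Data frame `bird_id`, `timestamp`, `lat`, `lon`.
#' @param dives Data frame `bird_id`, `timestamp`, `event`.
#' @param config A [study_config()].
#' @param species_map Optional data frame `bird_id`, `species`; movement
#'   states are then fitted per species.
#' @return List: `trackpoints` (annotated points with `foraging`, `state`,
#'   `trip_id`, `leg`), `trips` (per-trip rows), `embc_models` (named list).
#' @export
process_dataset <- function(fixes, dives, config = study_config(),
                            species_map = NULL) {
  tps <- lapply(split(fixes, fixes$bird_id), function(fb) {
    tr <- interpolate_track(fb, config)
    compute_kinematics(tr, config$nest_lat, config$nest_lon)
  })
  tp <- do.call(rbind, tps)
  rownames(tp) <- NULL
  tp$foraging <- aggregate_dives(dives, tp, config$sampling_interval_min)

  if (is.null(species_map)) {
    tp$species <- "all"
  } else {
    tp$species <- species_map$species[match(tp$bird_id, species_map$bird_id)]
  }
  tp$state <- NA_character_
  models <- list()
  for (spn in unique(tp$species)) {
    i <- which(tp$species == spn)
    m <- embc_fit(tp$ground_speed[i], tp$turning_angle[i])
    models[[spn]] <- m
    tp$state[i] <- embc_classify(m, tp$ground_speed[i], tp$turning_angle[i])
  }

  tp <- detect_trips(tp, config)
  trips <- attr(tp, "trips")
  tp$leg <- NA_character_
  for (tid in trips$trip_id) {
    i <- which(tp$trip_id %in% tid)
    if (length(i) >= 3) {
      tp$leg[i] <- split_legs(tp$dist_from_nest[i],
                              config$leg_fraction_threshold)
    }
  }
  list(trackpoints = tp, trips = trips, embc_models = models)
}

#' Run the full chain on a simulated dataset
#'
#' [process_dataset()] plus wind annotation and the commute filter, with
#' per-trip summaries.
#'
#' @param dataset A `simulated_dataset` from [simulate_colony()], or a
#'   list with `fixes`, `dives`, `field` and optionally `config`.
#' @param config A [study_config()]; defaults to the dataset's.
#' @param species_map Optional `bird_id`/`species` map; by default derived
#'   from the bird-id prefix of simulated birds.
#' @return List: `trackpoints`, `commute` (annotated commuting points),
#'   `trips`, `trip_summaries`, `embc_models`.
#' @export
run_pipeline <- function(dataset, config = NULL, species_map = NULL) {
  if (is.null(config)) {
    config <- if (!is.null(dataset$config)) dataset$config else study_config()
  }
  if (is.null(species_map)) {
    ids <- unique(dataset$fixes$bird_id)
    species_map <- data.frame(
      bird_id = ids,
      species = sub("_b[0-9]+$", "", ids),
      stringsAsFactors = FALSE)
  }
  proc <- process_dataset(dataset$fixes, dataset$dives, config, species_map)
  tp <- annotate_wind(proc$trackpoints, dataset$field,
                      config$wind_category_bounds)
  commute <- filter_commute(tp, config)
  summaries <- do.call(rbind, lapply(split(
    tp[!is.na(tp$trip_id), , drop = FALSE],
    tp$trip_id[!is.na(tp$trip_id)]),
    trip_summary, config = config))
  rownames(summaries) <- NULL
  list(trackpoints = tp, commute = commute, trips = proc$trips,
       trip_summaries = summaries, embc_models = proc$embc_models)
}

#' Recover the wind marginal effects for one species
#'
#' Runs the whole study design in silico: simulates a colony (default 8
#' birds x 5 trips) of the given species through a fresh diurnal katabatic
#' wind field, processes the tracks (regularisation, kinematics, dive
#' aggregation, movement states, trips/legs, wind annotation, commute
#' filter) and fits the ground-speed models: the species-level wind-by-
#' offset interaction model and the per-category wind-speed models.
#'
#' @param species A [species_params()] or the name of a packaged default.
#' @param n_birds,trips_per_bird Colony size.
#' @param seed Integer seed (drives both the wind field and the colony).
#' @param config A [study_config()].
#' @return List with `per45` (ground-speed change for a 45-degree tailward
#'   offset shift at mean wind speed), `tail5` / `head5` (signed
#'   ground-speed change per +5 m/s wind within the tailwind / headwind
#'   category), their standard errors, and the sample sizes used.
#' @export
recover_marginal_effects <- function(species, n_birds = 8,
                                     trips_per_bird = 5, seed = 1L,
                                     config = study_config()) {
  if (is.character(species)) species <- species_defaults(species)
  field <- simulate_wind_field(seed = seed + 1000L)
  ds <- simulate_colony(species, n_birds = n_birds,
                        trips_per_bird = trips_per_bird,
                        field = field, config = config, seed = seed)
  res <- run_pipeline(ds)
  d <- res$commute
  m <- fit_lmm(d, ground_speed ~ wind_speed * ddir_fw)
  dt <- d[d$wind_category == "tailwind", , drop = FALSE]
  dh <- d[d$wind_category == "headwind", , drop = FALSE]
  mt <- fit_lmm(dt, ground_speed ~ wind_speed)
  mh <- fit_lmm(dh, ground_speed ~ wind_speed)
  # delta-method SE of 45 * (beta_ddir + beta_int * mean wind)
  V <- as.matrix(stats::vcov(m$fit))
  wbar <- mean(d$wind_speed)
  g <- c("ddir_fw" = 1, "wind_speed:ddir_fw" = wbar)
  per45_var <- 45^2 * drop(t(g) %*% V[names(g), names(g)] %*% g)
  list(
    species = species$name,
    per45 = marginal_effect(m, "ddir_fw", 45),
    per45_se = sqrt(per45_var),
    tail5 = 5 * mt$coefficients["wind_speed", "estimate"],
    tail5_se = 5 * mt$coefficients["wind_speed", "se"],
    head5 = 5 * mh$coefficients["wind_speed", "estimate"],
    head5_se = 5 * mh$coefficients["wind_speed", "se"],
    n_commute = nrow(d), n_tail = nrow(dt), n_head = nrow(dh),
    models = list(interaction = m, tailwind = mt, headwind = mh))
}

#' Logger-burden arithmetic
#'
#' Percentage of a bird's body mass represented by a device.
#'
#' @param logger_mass_g Device mass, grams.
#' @param bird_mass_g Bird mass, grams.
#' @return Percentage (0-100 scale).
#' @export
logger_mass_percent <- function(logger_mass_g, bird_mass_g) {
  stopifnot(logger_mass_g > 0, bird_mass_g > 0)
  100 * logger_mass_g / bird_mass_g
}
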