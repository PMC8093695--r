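# toy track builder: distances from nest in km along due north, one bird
toy_track <- function(dists_km, foraging = NULL, t0 = NULL) {
  if (is.null(t0)) t0 <- as.POSIXct("2016-01-12 00:00:00", tz = "UTC")
  n <- length(dists_km)
  data.frame(
    bird_id = "b1",
    timestamp = t0 + (seq_len(n) - 1) * 900,
    dist_from_nest = dists_km,
    foraging = if (is.null(foraging)) rep(0L, n) else foraging)
}

test_that("trip detection needs both the distance threshold and dive data", {
  cfg <- study_config()
  tp <- toy_track(c(0, 5, 12, 5, 0), foraging = c(0, 0, 1, 0, 0))
  out <- detect_trips(tp, cfg)
  trips <- attr(out, "trips")
  expect_equal(nrow(trips), 1)
  expect_equal(trips$max_dist_from_nest, 12)
  expect_equal(sum(!is.na(out$trip_id)), 3)  # the three points beyond 2 km

  # 8 km maximum: below the 10-km trip threshold
  shallow <- detect_trips(toy_track(c(0, 8, 0), foraging = c(0, 1, 0)), cfg)
  expect_equal(nrow(attr(shallow, "trips")), 0)

  # far trip without any dive flag is not a foraging trip
  dry <- detect_trips(toy_track(c(0, 30, 50, 30, 0)), cfg)
  expect_equal(nrow(attr(dry, "trips")), 0)

  # two excursions by one bird become two trips
  two <- detect_trips(toy_track(c(0, 20, 0, 25, 0),
                                foraging = c(0, 1, 0, 1, 0)), cfg)
  expect_equal(nrow(attr(two, "trips")), 2)
})

test_that("leg splitting follows the distance-fraction rule", {
  expect_equal(split_legs(c(0, 5, 9, 10, 10, 9, 5, 0), f = 0.8),
               c("outbound", "outbound", "outbound", "middle", "middle",
                 "return", "return", "return"))
  # single-peak out-and-back: the peak alone is the middle
  expect_equal(split_legs(c(0, 10, 0)), c("outbound", "middle", "return"))
  expect_error(split_legs(c(0, 10)), "at least 3")

  # brute force over thresholds: higher f never lengthens the middle
  profile <- c(0, 3, 6, 9, 10, 10, 10, 8, 4, 1)
  mids <- sapply(c(0.5, 0.7, 0.9, 0.99),
                 function(f) sum(split_legs(profile, f) == "middle"))
  expect_true(all(diff(mids) <= 0))
  # f close to 1 keeps only the plateau interior as middle
  expect_equal(sum(split_legs(profile, 0.99) == "middle"), 1)
})

test_that("commute filter keeps non-foraging HL/HH points beyond the colony", {
  tp <- data.frame(
    bird_id = "b1",
    leg = c(rep("outbound", 5), rep("return", 5)),
    foraging = c(1, 1, 0, 0, 0, 0, 0, 0, 0, 0),
    state = c("HL", "HH", "LL", "LL", "HL", "HH", "HL", "HH", "HL", "HH"),
    dist_from_nest = c(5, 5, 5, 5, 1.5, 5, 5, 5, 5, 5),
    ground_speed = c(rep(8, 9), 0.3))
  kept <- filter_commute(tp, study_config())
  expect_equal(nrow(kept), 5)   # 2 diving, 2 LL, 1 inside 2 km removed
  # a slow HH point is retained: no ground-speed threshold is applied
  expect_true(any(kept$ground_speed == 0.3))

  lazy <- tp; lazy$state <- "LL"
  expect_warning(out <- filter_commute(lazy, study_config()),
                 "no commuting points")
  expect_equal(nrow(out), 0)
})

test_that("loop orientation from the shoelace sign of the projected polygon", {
  # square traversed E -> S -> W -> N from the nest is clockwise seen north-up
  lat <- c(-68.80, -68.90, -68.90, -68.80)
  lon <- c(77.90, 77.90, 77.60, 77.60)
  expect_equal(loop_direction(lat, lon, -68.80, 77.60), "clockwise")
  expect_equal(loop_direction(rev(lat), rev(lon), -68.80, 77.60),
               "counterclockwise")
  # out-and-back along one bearing encloses no area
  expect_equal(loop_direction(c(-68.8, -68.7, -68.6, -68.7),
                              c(77.7, 77.7, 77.7, 77.7), -68.9, 77.7),
               "undetermined")
})

test_that("trip summaries average the offset over commuting outbound points", {
  t0 <- as.POSIXct("2016-01-12 00:00:00", tz = "UTC")
  tp <- data.frame(
    bird_id = "b1", trip_id = "b1_trip01",
    timestamp = t0 + 0:5 * 900,
    lat = c(-68.80, -68.75, -68.70, -68.70, -68.75, -68.80),
    lon = c(77.70, 77.75, 77.80, 77.85, 77.80, 77.70),
    leg = c("outbound", "outbound", "outbound", "middle", "return", "return"),
    foraging = c(0, 0, 0, 1, 0, 0),
    state = c("HL", "HL", "HH", "LH", "HL", "HL"),
    ddir_fw = c(10, 20, 30, 170, 150, 140),
    dist_from_nest = c(3, 8, 12, 12, 8, 3))
  s <- trip_summary(tp, study_config())
  expect_equal(s$mean_outbound_ddir_fw, 20)
  expect_equal(s$max_dist_from_nest, 12)

  # a trip whose outbound is entirely foraging has no commuting offset
  tp2 <- tp
  tp2$foraging[tp2$leg == "outbound"] <- 1
  expect_message(s2 <- trip_summary(tp2, study_config()), "no commuting")
  expect_true(is.na(s2$mean_outbound_ddir_fw))
})
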